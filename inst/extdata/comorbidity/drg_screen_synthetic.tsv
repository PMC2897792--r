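category	drg
chf	127
arrhythmia	138
arrhythmia	139
valvular	135
valvular	136
valvular	137
pulm_circ	78
pvd	130
pvd	131
htn	134
paralysis	9
paralysis	12
paralysis	13
other_neuro	12
other_neuro	13
other_neuro	24
other_neuro	25
chronic_pulm	88
chronic_pulm	96
chronic_pulm	97
dm_uncomp	294
dm_uncomp	295
dm_comp	294
dm_comp	295
hypothyroid	300
hypothyroid	301
renal_failure	316
renal_failure	317
liver	205
liver	206
liver	207
liver	208
pud	176
pud	177
pud	178
aids	488
aids	489
aids	490
lymphoma	400
lymphoma	401
lymphoma	402
lymphoma	403
lymphoma	404
mets	82
mets	409
mets	410
mets	411
mets	412
mets	413
mets	414
solid_tumor	82
solid_tumor	409
solid_tumor	410
solid_tumor	411
solid_tumor	412
solid_tumor	413
solid_tumor	414
rheum	240
rheum	241
coag	397
obesity	288
wtloss	296
wtloss	297
wtloss	298
lytes	296
lytes	297
lytes	298
blood_loss_anemia	395
def_anemia	395
def_anemia	396
alcohol	433
alcohol	434
alcohol	435
alcohol	436
alcohol	437
drug	433
drug	434
drug	435
drug	436
drug	437
psychoses	430
depression	426
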