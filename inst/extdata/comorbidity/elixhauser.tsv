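method	category	icd9_prefix
elixhauser	chf	39891
elixhauser	chf	40201
elixhauser	chf	40211
elixhauser	chf	40291
elixhauser	chf	40401
elixhauser	chf	40411
elixhauser	chf	40491
elixhauser	chf	4254
elixhauser	chf	4255
elixhauser	chf	4257
elixhauser	chf	4258
elixhauser	chf	4259
elixhauser	chf	428
elixhauser	arrhythmia	4260
elixhauser	arrhythmia	42613
elixhauser	arrhythmia	4267
elixhauser	arrhythmia	4269
elixhauser	arrhythmia	4270
elixhauser	arrhythmia	4271
elixhauser	arrhythmia	4272
elixhauser	arrhythmia	4273
elixhauser	arrhythmia	4274
elixhauser	arrhythmia	4276
elixhauser	arrhythmia	4278
elixhauser	arrhythmia	4279
elixhauser	arrhythmia	7850
elixhauser	arrhythmia	V450
elixhauser	arrhythmia	V533
elixhauser	valvular	0932
elixhauser	valvular	394
elixhauser	valvular	395
elixhauser	valvular	396
elixhauser	valvular	397
elixhauser	valvular	424
elixhauser	valvular	7463
elixhauser	valvular	7464
elixhauser	valvular	7465
elixhauser	valvular	7466
elixhauser	valvular	V422
elixhauser	valvular	V433
elixhauser	pulm_circ	4150
elixhauser	pulm_circ	4151
elixhauser	pulm_circ	416
elixhauser	pulm_circ	4179
elixhauser	pvd	440
elixhauser	pvd	441
elixhauser	pvd	4420
elixhauser	pvd	4421
elixhauser	pvd	4428
elixhauser	pvd	4429
elixhauser	pvd	443
elixhauser	pvd	4471
elixhauser	pvd	5571
elixhauser	pvd	5579
elixhauser	pvd	V434
elixhauser	htn	401
elixhauser	htn	402
elixhauser	htn	403
elixhauser	htn	404
elixhauser	htn	405
elixhauser	paralysis	3341
elixhauser	paralysis	342
elixhauser	paralysis	343
elixhauser	paralysis	344
elixhauser	other_neuro	3319
elixhauser	other_neuro	3320
elixhauser	other_neuro	3334
elixhauser	other_neuro	3335
elixhauser	other_neuro	334
elixhauser	other_neuro	335
elixhauser	other_neuro	340
elixhauser	other_neuro	341
elixhauser	other_neuro	345
elixhauser	other_neuro	3481
elixhauser	other_neuro	3483
elixhauser	other_neuro	7803
elixhauser	other_neuro	7843
elixhauser	chronic_pulm	4168
elixhauser	chronic_pulm	4169
elixhauser	chronic_pulm	490
elixhauser	chronic_pulm	491
elixhauser	chronic_pulm	492
elixhauser	chronic_pulm	493
elixhauser	chronic_pulm	494
elixhauser	chronic_pulm	495
elixhauser	chronic_pulm	496
elixhauser	chronic_pulm	500
elixhauser	chronic_pulm	501
elixhauser	chronic_pulm	502
elixhauser	chronic_pulm	503
elixhauser	chronic_pulm	504
elixhauser	chronic_pulm	505
elixhauser	chronic_pulm	5064
elixhauser	dm_uncomp	2500
elixhauser	dm_uncomp	2501
elixhauser	dm_uncomp	2502
elixhauser	dm_uncomp	2503
elixhauser	dm_comp	2504
elixhauser	dm_comp	2505
elixhauser	dm_comp	2506
elixhauser	dm_comp	2507
elixhauser	dm_comp	2508
elixhauser	dm_comp	2509
elixhauser	hypothyroid	2409
elixhauser	hypothyroid	243
elixhauser	hypothyroid	244
elixhauser	hypothyroid	2461
elixhauser	hypothyroid	2468
elixhauser	renal_failure	585
elixhauser	renal_failure	586
elixhauser	renal_failure	5880
elixhauser	renal_failure	V420
elixhauser	renal_failure	V451
elixhauser	renal_failure	V56
elixhauser	liver	570
elixhauser	liver	5712
elixhauser	liver	5714
elixhauser	liver	5715
elixhauser	liver	5716
elixhauser	liver	5718
elixhauser	liver	5719
elixhauser	liver	5722
elixhauser	liver	5723
elixhauser	liver	5724
elixhauser	liver	5728
elixhauser	liver	5733
elixhauser	liver	5734
elixhauser	liver	5738
elixhauser	liver	5739
elixhauser	liver	V427
elixhauser	pud	5317
elixhauser	pud	5319
elixhauser	pud	5327
elixhauser	pud	5329
elixhauser	pud	5337
elixhauser	pud	5339
elixhauser	pud	5347
elixhauser	pud	5349
elixhauser	aids	042
elixhauser	aids	043
elixhauser	aids	044
elixhauser	lymphoma	200
elixhauser	lymphoma	201
elixhauser	lymphoma	202
elixhauser	lymphoma	2030
elixhauser	lymphoma	2386
elixhauser	mets	196
elixhauser	mets	197
elixhauser	mets	198
elixhauser	mets	1990
elixhauser	mets	1991
elixhauser	solid_tumor	140
elixhauser	solid_tumor	141
elixhauser	solid_tumor	142
elixhauser	solid_tumor	143
elixhauser	solid_tumor	144
elixhauser	solid_tumor	145
elixhauser	solid_tumor	146
elixhauser	solid_tumor	147
elixhauser	solid_tumor	148
elixhauser	solid_tumor	149
elixhauser	solid_tumor	150
elixhauser	solid_tumor	151
elixhauser	solid_tumor	152
elixhauser	solid_tumor	153
elixhauser	solid_tumor	154
elixhauser	solid_tumor	155
elixhauser	solid_tumor	156
elixhauser	solid_tumor	157
elixhauser	solid_tumor	158
elixhauser	solid_tumor	159
elixhauser	solid_tumor	160
elixhauser	solid_tumor	161
elixhauser	solid_tumor	162
elixhauser	solid_tumor	163
elixhauser	solid_tumor	164
elixhauser	solid_tumor	165
elixhauser	solid_tumor	166
elixhauser	solid_tumor	167
elixhauser	solid_tumor	168
elixhauser	solid_tumor	169
elixhauser	solid_tumor	170
elixhauser	solid_tumor	171
elixhauser	solid_tumor	172
elixhauser	solid_tumor	174
elixhauser	solid_tumor	175
elixhauser	solid_tumor	176
elixhauser	solid_tumor	177
elixhauser	solid_tumor	178
elixhauser	solid_tumor	179
elixhauser	solid_tumor	180
elixhauser	solid_tumor	181
elixhauser	solid_tumor	182
elixhauser	solid_tumor	183
elixhauser	solid_tumor	184
elixhauser	solid_tumor	185
elixhauser	solid_tumor	186
elixhauser	solid_tumor	187
elixhauser	solid_tumor	188
elixhauser	solid_tumor	189
elixhauser	solid_tumor	190
elixhauser	solid_tumor	191
elixhauser	solid_tumor	192
elixhauser	solid_tumor	193
elixhauser	solid_tumor	194
elixhauser	solid_tumor	195
elixhauser	rheum	7010
elixhauser	rheum	710
elixhauser	rheum	714
elixhauser	rheum	720
elixhauser	rheum	725
elixhauser	coag	286
elixhauser	coag	2871
elixhauser	coag	2873
elixhauser	coag	2874
elixhauser	coag	2875
elixhauser	obesity	2780
elixhauser	wtloss	260
elixhauser	wtloss	261
elixhauser	wtloss	262
elixhauser	wtloss	263
elixhauser	lytes	2536
elixhauser	lytes	276
elixhauser	blood_loss_anemia	2800
elixhauser	def_anemia	2801
elixhauser	def_anemia	2808
elixhauser	def_anemia	2809
elixhauser	def_anemia	281
elixhauser	alcohol	2652
elixhauser	alcohol	291
elixhauser	alcohol	303
elixhauser	alcohol	3050
elixhauser	drug	292
elixhauser	drug	304
elixhauser	drug	3052
elixhauser	drug	3053
elixhauser	drug	3054
elixhauser	drug	3055
elixhauser	drug	3056
elixhauser	drug	3057
elixhauser	drug	3058
elixhauser	drug	3059
elixhauser	psychoses	295
elixhauser	psychoses	297
elixhauser	psychoses	298
elixhauser	depression	2962
elixhauser	depression	2963
elixhauser	depression	2965
elixhauser	depression	3004
elixhauser	depression	309
elixhauser	depression	311
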