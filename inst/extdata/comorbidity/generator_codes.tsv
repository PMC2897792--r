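category	code	weight
chf	4280	0.6
chf	4254	0.25
chf	39891	0.15
pvd	4439	0.5
pvd	4400	0.3
pvd	4429	0.2
cvd	4340	0.5
cvd	4359	0.3
cvd	36234	0.2
dementia	2900	0.6
dementia	3310	0.4
chronic_pulm	4912	0.5
chronic_pulm	4960	0.3
chronic_pulm	4168	0.2
dm_uncomp	2500	0.6
dm_uncomp	25000	0.4
dm_comp	2504	0.5
dm_comp	2506	0.5
renal_failure	585	0.6
renal_failure	5880	0.2
renal_failure	40391	0.2
mild_liver	5715	0.6
mild_liver	5712	0.4
cancer	1629	0.5
cancer	1830	0.3
cancer	2029	0.2
mets	1970	0.6
mets	1983	0.4
arrhythmia	42731	0.7
arrhythmia	4270	0.3
valvular	4240	0.6
valvular	3960	0.4
lytes	2762	0.5
lytes	2765	0.5
coag	2866	0.6
coag	2875	0.4
wtloss	2639	0.6
wtloss	2630	0.4
def_anemia	2809	0.6
def_anemia	2811	0.4
depression	311	0.6
depression	3004	0.4
htn	4019	0.7
htn	4011	0.3
pud	5319	0.6
pud	53190	0.4
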