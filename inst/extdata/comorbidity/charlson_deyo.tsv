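method	category	icd9_prefix
charlson_deyo	mi	410
charlson_deyo	mi	412
charlson_deyo	chf	428
charlson_deyo	pvd	4439
charlson_deyo	pvd	441
charlson_deyo	pvd	7854
charlson_deyo	pvd	V434
charlson_deyo	cvd	430
charlson_deyo	cvd	431
charlson_deyo	cvd	432
charlson_deyo	cvd	433
charlson_deyo	cvd	434
charlson_deyo	cvd	435
charlson_deyo	cvd	436
charlson_deyo	cvd	437
charlson_deyo	cvd	438
charlson_deyo	dementia	290
charlson_deyo	copd	490
charlson_deyo	copd	491
charlson_deyo	copd	492
charlson_deyo	copd	493
charlson_deyo	copd	494
charlson_deyo	copd	495
charlson_deyo	copd	496
charlson_deyo	copd	500
charlson_deyo	copd	501
charlson_deyo	copd	502
charlson_deyo	copd	503
charlson_deyo	copd	504
charlson_deyo	copd	505
charlson_deyo	copd	5064
charlson_deyo	rheum	7100
charlson_deyo	rheum	7101
charlson_deyo	rheum	7104
charlson_deyo	rheum	7140
charlson_deyo	rheum	7141
charlson_deyo	rheum	7142
charlson_deyo	rheum	71481
charlson_deyo	rheum	5171
charlson_deyo	rheum	725
charlson_deyo	pud	531
charlson_deyo	pud	532
charlson_deyo	pud	533
charlson_deyo	pud	534
charlson_deyo	mild_liver	5712
charlson_deyo	mild_liver	5714
charlson_deyo	mild_liver	5715
charlson_deyo	mild_liver	5716
charlson_deyo	dm	2500
charlson_deyo	dm	2501
charlson_deyo	dm	2502
charlson_deyo	dm	2503
charlson_deyo	dm	2507
charlson_deyo	dm_comp	2504
charlson_deyo	dm_comp	2505
charlson_deyo	dm_comp	2506
charlson_deyo	paralysis	342
charlson_deyo	paralysis	3441
charlson_deyo	renal	582
charlson_deyo	renal	5830
charlson_deyo	renal	5831
charlson_deyo	renal	5832
charlson_deyo	renal	5834
charlson_deyo	renal	5836
charlson_deyo	renal	5837
charlson_deyo	renal	585
charlson_deyo	renal	586
charlson_deyo	renal	5880
charlson_deyo	cancer	140
charlson_deyo	cancer	141
charlson_deyo	cancer	142
charlson_deyo	cancer	143
charlson_deyo	cancer	144
charlson_deyo	cancer	145
charlson_deyo	cancer	146
charlson_deyo	cancer	147
charlson_deyo	cancer	148
charlson_deyo	cancer	149
charlson_deyo	cancer	150
charlson_deyo	cancer	151
charlson_deyo	cancer	152
charlson_deyo	cancer	153
charlson_deyo	cancer	154
charlson_deyo	cancer	155
charlson_deyo	cancer	156
charlson_deyo	cancer	157
charlson_deyo	cancer	158
charlson_deyo	cancer	159
charlson_deyo	cancer	160
charlson_deyo	cancer	161
charlson_deyo	cancer	162
charlson_deyo	cancer	163
charlson_deyo	cancer	164
charlson_deyo	cancer	165
charlson_deyo	cancer	166
charlson_deyo	cancer	167
charlson_deyo	cancer	168
charlson_deyo	cancer	169
charlson_deyo	cancer	170
charlson_deyo	cancer	171
charlson_deyo	cancer	172
charlson_deyo	cancer	174
charlson_deyo	cancer	175
charlson_deyo	cancer	176
charlson_deyo	cancer	177
charlson_deyo	cancer	178
charlson_deyo	cancer	179
charlson_deyo	cancer	180
charlson_deyo	cancer	181
charlson_deyo	cancer	182
charlson_deyo	cancer	183
charlson_deyo	cancer	184
charlson_deyo	cancer	185
charlson_deyo	cancer	186
charlson_deyo	cancer	187
charlson_deyo	cancer	188
charlson_deyo	cancer	189
charlson_deyo	cancer	190
charlson_deyo	cancer	191
charlson_deyo	cancer	192
charlson_deyo	cancer	193
charlson_deyo	cancer	194
charlson_deyo	cancer	195
charlson_deyo	cancer	200
charlson_deyo	cancer	201
charlson_deyo	cancer	202
charlson_deyo	cancer	203
charlson_deyo	cancer	204
charlson_deyo	cancer	205
charlson_deyo	cancer	206
charlson_deyo	cancer	207
charlson_deyo	cancer	208
charlson_deyo	severe_liver	4560
charlson_deyo	severe_liver	4561
charlson_deyo	severe_liver	4562
charlson_deyo	severe_liver	5722
charlson_deyo	severe_liver	5723
charlson_deyo	severe_liver	5724
charlson_deyo	severe_liver	5728
charlson_deyo	mets	196
charlson_deyo	mets	197
charlson_deyo	mets	198
charlson_deyo	mets	1990
charlson_deyo	mets	1991
charlson_deyo	aids	042
charlson_deyo	aids	043
charlson_deyo	aids	044
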