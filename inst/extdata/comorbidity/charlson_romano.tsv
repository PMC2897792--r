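method	category	icd9_prefix
charlson_romano	mi	410
charlson_romano	mi	412
charlson_romano	chf	428
charlson_romano	chf	4254
charlson_romano	chf	4293
charlson_romano	chf	39891
charlson_romano	chf	40201
charlson_romano	chf	40211
charlson_romano	chf	40291
charlson_romano	chf	40401
charlson_romano	chf	40411
charlson_romano	chf	40491
charlson_romano	pvd	440
charlson_romano	pvd	441
charlson_romano	pvd	4420
charlson_romano	pvd	4421
charlson_romano	pvd	4428
charlson_romano	pvd	4429
charlson_romano	pvd	4431
charlson_romano	pvd	4432
charlson_romano	pvd	4438
charlson_romano	pvd	4439
charlson_romano	pvd	4471
charlson_romano	pvd	5571
charlson_romano	pvd	5579
charlson_romano	pvd	7854
charlson_romano	pvd	V434
charlson_romano	cvd	430
charlson_romano	cvd	431
charlson_romano	cvd	432
charlson_romano	cvd	433
charlson_romano	cvd	434
charlson_romano	cvd	435
charlson_romano	cvd	436
charlson_romano	cvd	437
charlson_romano	cvd	438
charlson_romano	cvd	36234
charlson_romano	cvd	7843
charlson_romano	dementia	290
charlson_romano	dementia	2941
charlson_romano	dementia	3310
charlson_romano	dementia	3311
charlson_romano	dementia	3312
charlson_romano	copd	490
charlson_romano	copd	491
charlson_romano	copd	492
charlson_romano	copd	493
charlson_romano	copd	494
charlson_romano	copd	495
charlson_romano	copd	496
charlson_romano	copd	500
charlson_romano	copd	501
charlson_romano	copd	502
charlson_romano	copd	503
charlson_romano	copd	504
charlson_romano	copd	505
charlson_romano	copd	5064
charlson_romano	copd	4168
charlson_romano	copd	4169
charlson_romano	rheum	7100
charlson_romano	rheum	7101
charlson_romano	rheum	7104
charlson_romano	rheum	7108
charlson_romano	rheum	7109
charlson_romano	rheum	714
charlson_romano	rheum	725
charlson_romano	rheum	7285
charlson_romano	pud	531
charlson_romano	pud	532
charlson_romano	pud	533
charlson_romano	pud	534
charlson_romano	mild_liver	5712
charlson_romano	mild_liver	5714
charlson_romano	mild_liver	5715
charlson_romano	mild_liver	5716
charlson_romano	mild_liver	5718
charlson_romano	mild_liver	5719
charlson_romano	mild_liver	5733
charlson_romano	dm	2500
charlson_romano	dm	2501
charlson_romano	dm	2502
charlson_romano	dm	2503
charlson_romano	dm_comp	2504
charlson_romano	dm_comp	2505
charlson_romano	dm_comp	2506
charlson_romano	dm_comp	2507
charlson_romano	dm_comp	2508
charlson_romano	dm_comp	2509
charlson_romano	paralysis	342
charlson_romano	paralysis	344
charlson_romano	renal	582
charlson_romano	renal	583
charlson_romano	renal	585
charlson_romano	renal	586
charlson_romano	renal	5880
charlson_romano	renal	40301
charlson_romano	renal	40311
charlson_romano	renal	40391
charlson_romano	renal	V420
charlson_romano	renal	V451
charlson_romano	renal	V56
charlson_romano	cancer	140
charlson_romano	cancer	141
charlson_romano	cancer	142
charlson_romano	cancer	143
charlson_romano	cancer	144
charlson_romano	cancer	145
charlson_romano	cancer	146
charlson_romano	cancer	147
charlson_romano	cancer	148
charlson_romano	cancer	149
charlson_romano	cancer	150
charlson_romano	cancer	151
charlson_romano	cancer	152
charlson_romano	cancer	153
charlson_romano	cancer	154
charlson_romano	cancer	155
charlson_romano	cancer	156
charlson_romano	cancer	157
charlson_romano	cancer	158
charlson_romano	cancer	159
charlson_romano	cancer	160
charlson_romano	cancer	161
charlson_romano	cancer	162
charlson_romano	cancer	163
charlson_romano	cancer	164
charlson_romano	cancer	165
charlson_romano	cancer	166
charlson_romano	cancer	167
charlson_romano	cancer	168
charlson_romano	cancer	169
charlson_romano	cancer	170
charlson_romano	cancer	171
charlson_romano	cancer	172
charlson_romano	cancer	174
charlson_romano	cancer	175
charlson_romano	cancer	176
charlson_romano	cancer	177
charlson_romano	cancer	178
charlson_romano	cancer	179
charlson_romano	cancer	180
charlson_romano	cancer	181
charlson_romano	cancer	182
charlson_romano	cancer	183
charlson_romano	cancer	184
charlson_romano	cancer	185
charlson_romano	cancer	186
charlson_romano	cancer	187
charlson_romano	cancer	188
charlson_romano	cancer	189
charlson_romano	cancer	190
charlson_romano	cancer	191
charlson_romano	cancer	192
charlson_romano	cancer	193
charlson_romano	cancer	194
charlson_romano	cancer	195
charlson_romano	cancer	200
charlson_romano	cancer	201
charlson_romano	cancer	202
charlson_romano	cancer	203
charlson_romano	cancer	204
charlson_romano	cancer	205
charlson_romano	cancer	206
charlson_romano	cancer	207
charlson_romano	cancer	208
charlson_romano	severe_liver	4560
charlson_romano	severe_liver	4561
charlson_romano	severe_liver	4562
charlson_romano	severe_liver	5722
charlson_romano	severe_liver	5723
charlson_romano	severe_liver	5724
charlson_romano	severe_liver	5728
charlson_romano	severe_liver	5730
charlson_romano	mets	196
charlson_romano	mets	197
charlson_romano	mets	198
charlson_romano	mets	199
charlson_romano	aids	042
charlson_romano	aids	043
charlson_romano	aids	044
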