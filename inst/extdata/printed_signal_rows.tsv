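drug	stratum	soc	pt	a	ror	ror_l95	ror_u95	prr	chi2	ic	ic025	ebgm	ebgm05
baloxavir	all	General disorders and administration site conditions	No adverse event	268	54.84	46.89	64.15	34.14	8015.30	4.97	4.62	31.43	26.87
baloxavir	all	Psychiatric disorders	Abnormal behaviour	21	12.28	7.89	19.11	11.75	203.40	3.53	2.37	11.54	7.42
baloxavir	all	Psychiatric disorders	Delirium	5	9.01	3.71	21.89	8.91	34.67	3.14	0.69	8.80	3.62
baloxavir	all	Injury, poisoning and procedural complications	Off label use	263	5.60	4.80	6.54	3.85	610.84	1.94	1.72	3.82	3.28
baloxavir	all	Injury, poisoning and procedural complications	Intentional product use issue	203	97.43	81.73	116.14	66.45	11374.74	5.85	5.28	57.57	48.30
baloxavir	all	Injury, poisoning and procedural complications	Product administered to patient of inappropriate age	15	6.16	3.67	10.33	5.99	62.03	2.57	1.47	5.94	3.54
baloxavir	all	Injury, poisoning and procedural complications	Medication error	8	6.36	3.15	12.84	6.26	35.10	2.63	1.00	6.21	3.07
baloxavir	all	Immune system disorders	Anaphylactic shock	12	21.68	12.10	38.84	21.11	222.50	4.35	2.25	20.44	11.41
oseltamivir	all	Psychiatric disorders	Abnormal behaviour	34	20.08	14.09	28.62	18.68	553.34	4.18	3.14	18.13	12.72
oseltamivir	all	Psychiatric disorders	Delirium	17	30.44	18.54	49.99	29.36	443.77	4.81	2.83	27.99	17.04
oseltamivir	all	Skin and subcutaneous tissue disorders	Stevens-Johnson syndrome	11	12.10	6.61	22.14	11.84	107.18	3.54	1.80	11.62	6.35
oseltamivir	all	Eye disorders	Visual impairment	7	5.77	2.72	12.21	5.70	26.91	2.50	0.79	5.65	2.67
oseltamivir	all	Eye disorders	Blindness	5	12.67	5.20	30.87	12.54	52.02	3.62	0.85	12.30	5.05
oseltamivir	all	Eye disorders	Central vision loss	4	1163.80	212.64	6369.79	1153.78	1535.74	8.59	1.13	385.26	70.39
oseltamivir	all	Eye disorders	Acute macular outer retinopathy	3	1741.93	180.85	16777.66	1730.67	1296.52	8.76	0.70	433.42	45.00
oseltamivir	all	Blood and lymphatic system disorders	Leukopenia	10	7.99	4.25	15.01	7.84	59.02	2.95	1.39	7.75	4.12
oseltamivir	all	Blood and lymphatic system disorders	Normocytic anaemia	4	166.25	54.52	506.98	164.83	506.62	7.00	0.96	128.42	42.11
oseltamivir	all	Vascular disorders	Shock	5	5.61	2.31	13.59	5.56	18.55	2.46	0.41	5.51	2.27
oseltamivir	all	Cardiac disorders	Supraventricular tachycardia	4	13.60	5.03	36.82	13.49	45.25	3.72	0.55	13.21	4.88
oseltamivir	all	Respiratory, thoracic and mediastinal disorders	Acute respiratory distress syndrome	7	7.82	3.69	16.59	7.72	40.49	2.93	1.02	7.63	3.60
oseltamivir	all	Respiratory, thoracic and mediastinal disorders	Obliterative bronchiolitis	5	45.55	18.25	113.70	45.07	199.90	5.39	1.20	41.88	16.78
oseltamivir	all	Nervous system disorders	Tremor	12	4.33	2.43	7.69	4.24	29.67	2.08	0.96	4.22	2.37
oseltamivir	all	Nervous system disorders	Loss of consciousness	9	4.38	2.26	8.49	4.31	22.83	2.10	0.77	4.29	2.21
oseltamivir	all	Investigations	Body temperature decreased	6	29.70	13.01	67.81	29.33	156.33	4.81	1.41	27.96	12.25
oseltamivir	all	Investigations	Influenza A virus test positive	4	211.59	67.13	666.95	209.78	609.53	7.27	0.98	154.10	48.89
oseltamivir	all	Infections and infestations	Pneumonia	18	3.45	2.15	5.53	3.35	29.86	1.74	0.92	3.34	2.08
oseltamivir	all	Infections and infestations	Influenza	14	5.33	3.12	9.10	5.20	47.35	2.37	1.28	5.16	3.03
oseltamivir	all	Ear and labyrinth disorders	Ear inflammation	3	435.48	97.19	1951.20	432.67	738.31	7.95	0.56	247.67	55.28
oseltamivir	all	Metabolism and nutrition disorders	Dehydration	15	7.79	4.64	13.07	7.57	84.80	2.90	1.71	7.49	4.46
baloxavir	M	Immune system disorders	Anaphylactic shock	10	55.33	29.22	104.80	52.35	502.33	5.70	2.34	52.16	27.54
oseltamivir	F	Skin and subcutaneous tissue disorders	Stevens-Johnson syndrome	11	87.07	47.33	160.16	82.26	879.74	6.36	2.59	81.91	44.53
oseltamivir	F	Skin and subcutaneous tissue disorders	Toxic epidermal necrolysis	4	36.84	13.67	99.24	36.11	136.36	5.17	0.78	36.04	13.38
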