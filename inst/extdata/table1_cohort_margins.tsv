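variable	statistic	level	hc	ad
n	count	total	100	75
age	mean	.	71.0	68.6
age	sd	.	4.4	8.6
gender	count	m	46	41
gender	count	f	54	34
mmse	mean	.	28.9	22.6
mmse	sd	.	1.9	5.1
gds	mean	.	2.1	2.8
gds	sd	.	2.6	2.1
bmi	mean	.	25.9	24.9
bmi	sd	.	4.5	4.3
apoe_e4_count	count	2	2	5
apoe_e4_count	count	1	18	30
apoe_e4_count	count	0	38	18
arterial_hypertension	count	yes	42	29
arterial_hypertension	count	no	58	46
diabetes_mellitus	count	yes	5	1
diabetes_mellitus	count	no	95	74
rheumatoid_arthritis	count	yes	7	2
rheumatoid_arthritis	count	no	93	73
nsaids	count	yes	24	18
nsaids	count	no	76	57
anticoagulants	count	yes	4	2
anticoagulants	count	no	96	73
antihypertensives	count	yes	41	33
antihypertensives	count	no	59	42
antidiabetics	count	yes	4	0
antidiabetics	count	no	96	75
statins	count	yes	11	12
statins	count	no	89	63
antidepressants	count	yes	6	23
antidepressants	count	no	94	52
ache_inhibitors	count	yes	0	43
ache_inhibitors	count	no	100	32
csf_abeta42	mean	.	NA	478.7
csf_abeta42	sd	.	NA	101.7
csf_ttau	mean	.	NA	727.1
csf_ttau	sd	.	NA	386.5
csf_ptau	mean	.	NA	90.9
csf_ptau	sd	.	NA	38.9
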