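accession	sample	cluster	group	sum_tpm	avg_tpm	max_tpm
GSM125353	Bronchial brushings, former smoker	N	top	43563.92	251.81	40054.67
GSM574	Central retina (macula)	N	top	33159.24	191.67	26692.01
GSM383793	Mammary gland, ductal carcinoma in situ	C	top	29781.50	172.15	25275.20
GSM1730	Breast, ductal carcinoma in situ	C	top	29575.98	170.96	25125.63
GSM125352	Bronchial brushings, former smoker	N	top	29184.64	168.70	24955.09
GSM383797	Mammary gland, ductal carcinoma	C	top	27222.30	157.35	22422.27
GSM194651	Oral biopsy	N	top	27066.16	156.45	21312.29
GSM112808	Neuroblastoma, primary tumor, stage 4S	C	top	25944.14	149.97	17365.83
GSM14753	Breast carcinoma metastasis to lung	C	top	23941.22	138.39	20247.08
GSM383794	Mammary gland, ductal carcinoma in situ	C	top	23570.83	136.25	18977.90
GSM1731	Breast, ductal carcinoma in situ	C	top	23346.84	134.95	18746.14
GSM383893	Gallbladder tubular adenocarcinoma	C	top	23262.07	134.46	20154.48
GSM384016	Vascular endothelium, hemangioma, benign hyperplasia	D	top	22688.19	131.15	12514.88
GSM112809	Neuroblastoma, primary tumor, stage 4S	C	top	22633.99	130.83	11595.94
GSM1516	Hemangioma tumor	C	top	22622.41	130.77	12500.82
GSM194652	Oral biopsy	N	top	21279.52	123.00	11932.33
GSM383807	Mammary gland, ductal carcinoma in situ	C	top	20570.15	118.90	16071.37
GSM383800	Breast carcinoma cell line	IV	top	20467.40	118.31	12710.80
GSM383790	Mammary gland, ductal carcinoma	C	top	20417.00	118.02	15536.62
GSM383946	Whole body, fetal	N	top	20274.33	117.19	9698.99
GSM383812	Mammary gland, ductal carcinoma	C	top	20036.49	115.82	13377.93
GSM688	Breast, ductal carcinoma in situ	C	top	19968.16	115.42	15538.48
GSM383775	Cortex, pooled sample	N	top	19926.52	115.18	13701.49
GSM85616	Bronchial epithelium	N	top	19665.60	113.67	15918.74
GSM85611	Bronchial epithelium	N	top	19653.98	113.61	15655.95
GSM194386	Metaplastic bronchial epithelium	D	top	19376.31	112.00	14577.13
GSM125358	Bronchial brushings, never smoker	N	top	19369.05	111.96	14172.30
GSM383895	Gallbladder	N	top	19320.00	111.68	15346.14
GSM383804	Breast carcinoma cell line	IV	top	19247.28	111.26	9389.55
GSM1733	Mammary gland, ductal invasive in situ carcinoma	C	top	19126.03	110.56	14594.68
GSM112812	Neuroblastoma, primary tumor, stage 4	C	top	18914.78	109.33	12349.04
GSM573	Peripheral retina	N	top	18817.72	108.77	12293.99
GSM572	Peripheral retina	N	top	18781.47	108.56	8727.76
GSM194377	Nonsmall cell lung cancer: squamous cell carcinoma in situ	C	top	18122.08	104.75	14601.68
GSM14781	Brain desmoplastic medulloblastoma	C	top	18106.48	104.66	11244.70
GSM383806	Breast carcinoma cell line	IV	top	17991.89	104.00	8886.81
GSM125343	Bronchial brushings, former smoker	N	top	17662.13	102.09	12756.35
GSM125337	Bronchial brushings, current smoker	N	top	17598.56	101.73	12699.28
GSM383710	Ependymoma	C	top	17524.27	101.30	10222.49
GSM82458	Hippocampus	N	top	17289.52	99.94	8268.90
GSM125349	Bronchial brushings, former smoker	N	top	17225.16	99.57	13193.26
GSM296391	Lung biopsy	N	top	17223.67	99.56	13839.55
GSM125339	Bronchial brushings, current smoker	N	top	16871.13	97.52	10737.09
GSM194379	Nonsmall cell lung cancer: squamous cell carcinoma in situ	C	top	16572.81	95.80	12713.33
GSM125351	Bronchial brushings, former smoker	N	top	16456.57	95.12	11137.34
GSM125347	Bronchial brushings, former smoker	N	top	16306.85	94.26	11835.62
GSM37212	Adrenal cortex affected by primary pigmented nodular adrenocortical disease	D	top	16221.46	93.77	4205.56
GSM125336	Bronchial brushings, current smoker	N	top	16090.33	93.01	11242.21
GSM194375	Nonsmall cell lung cancer: squamous cell carcinoma in situ	C	top	15715.04	90.84	11679.51
GSM383868	Colon carcinoma, cell line	IV	bottom	4179.31	24.16	422.91
GSM14780	Gastric epithelial tissue from the antrum	N	bottom	4169.95	24.10	1615.39
GSM14807	Lung, poorly differentiated adenocarcinoma with lymphoplasmacytic infiltration	C	bottom	4146.18	23.97	460.69
GSM383998	Gastroesophageal junction adenocarcinoma	C	bottom	4141.08	23.94	1351.60
GSM668	Kidney, embryonic cell line 293, uninduced cells	IV	bottom	4119.01	23.81	920.45
GSM3244	AIDS-KS lesion	D	bottom	4107.85	23.74	1245.47
GSM383914	Lung, tumor associated (focal fibrosis and chronic inflammation)	D	bottom	4103.62	23.72	606.45
GSM3245	CD4+ T cells	N	bottom	4088.74	23.63	978.17
GSM14734	Medulloblastoma, cerebellum	C	bottom	4081.98	23.60	804.90
GSM14760	Stomach, poorly differentiated carcinoma	C	bottom	4081.16	23.59	1340.95
GSM14751	Skin, melanoma	C	bottom	4072.22	23.54	2497.12
GSM383865	Colon carcinoma, cell line	IV	bottom	4048.02	23.40	404.80
GSM383753	Medulloblastoma	C	bottom	3987.16	23.05	1069.73
GSM383867	Colon carcinoma, cell line	IV	bottom	3961.32	22.90	506.24
GSM747	Colon, cancer cell line	IV	bottom	3945.42	22.81	673.61
GSM383892	Gallbladder adenocarcinoma	C	bottom	3909.95	22.60	651.66
GSM311354	CD15+ myeloid progenitor cells	N	bottom	3859.27	22.31	1108.11
GSM82459	Spermatozoa	N	bottom	3814.90	22.05	1288.15
GSM82243	Spermatozoa, pooled sample	N	bottom	3811.16	22.03	1429.18
GSM180670	Lymphocytes from children 1–4 years old (pooled samples)	N	bottom	3794.27	21.93	843.17
GSM383866	Colon carcinoma, cell line	IV	bottom	3746.12	21.65	378.40
GSM14784	Bone marrow	N	bottom	3740.58	21.62	962.65
GSM136195	Cord blood-derived activated Th1 cells	N	bottom	3668.81	21.21	777.29
GSM383787	Breast stroma, ductal carcinoma in situ associated	D	bottom	3663.78	21.18	334.67
GSM66698	HL-60 cells	IV	bottom	3661.81	21.17	920.25
GSM383894	Gallbladder tubular adenocarcinoma	C	bottom	3643.40	21.06	624.22
GSM37337	Primary bronchial epithelial cells	IV	bottom	3604.30	20.83	804.84
GSM383970	Retinoblastoma	C	bottom	3561.82	20.59	384.45
GSM383852	Cartilage chondrosarcoma cell line	IV	bottom	3502.94	20.25	515.14
GSM7800	Primary gastric cancer, poorly differentiated (scirrhous type)	C	bottom	3413.27	19.73	636.37
GSM383840	Mammary myoepithelium, CD10+ cells	N	bottom	3364.85	19.45	291.33
GSM66712	HL-60 cells exposed to 2.45 GHz radiofrequency for 2 h	IV	bottom	3293.77	19.04	982.36
GSM194649	Oral brushing	N	bottom	3290.72	19.02	996.85
GSM383915	Lymph node, B-cell lymphoma	C	bottom	3166.97	18.31	555.61
GSM383902	Leukocytes	N	bottom	2991.69	17.29	439.34
GSM383803	Breast carcinoma cell line	IV	bottom	2988.12	17.27	597.62
GSM383801	Breast carcinoma cell line	IV	bottom	2977.71	17.21	297.77
GSM784	Gastric epithelial tissues	N	bottom	2970.06	17.17	673.21
GSM384002	Stomach	N	bottom	2813.83	16.26	654.38
GSM383903	Liver cholangiocarcinoma metastasis	C	bottom	2736.32	15.82	1575.46
GSM389908	Total blood after EPO treatment, pooled sample	D	bottom	2684.90	15.52	747.69
GSM14775	Skin, primary malignant melanoma	C	bottom	2612.99	15.10	653.25
GSM66714	HL-60 cells exposed to 2.45 GHz radiofrequency for 6 h	IV	bottom	1879.82	10.87	639.52
GSM383937	Pancreas	N	bottom	1813.11	10.48	278.94
GSM135389	Skeletal muscle, 5 days training young men	N	bottom	1673.61	9.67	435.14
GSM135392	Skeletal muscle, detraining young men	N	bottom	1670.43	9.66	510.41
GSM389906	Total blood, pooled sample	N	bottom	1511.12	8.73	436.55
GSM135388	Skeletal muscle, pretraining young men	N	bottom	1091.72	6.31	327.52
GSM389907	Total blood during EPO treatment, pooled sample	D	bottom	811.75	4.69	162.35
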