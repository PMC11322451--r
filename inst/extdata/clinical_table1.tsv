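patient_id	sex	age_at_surgery	age_of_onset	duration_of_epilepsy	resection	side	mri_finding	delay_baseline_to_surgery_months	delay_surgery_to_scan1_months	delay_surgery_to_scan2_months	follow_up_months	engel_class	postoperative_deficit	delay_to_recovery_months
1	M	35	30	5	Insula (subtotal) + Fop	L	FCD	0.5	5.3	13.4	36	IIB	Aphasia	1
2	M	37	27	10	Anterior insula + Fop	R	N	6.9	6.1	12.5	60	IA	None	NA
3	F	27	9	18	Anterior insula + Fop	R	N	2.4	7	13.2	36	IA	None	NA
4	F	38	5	33	Anterior insula + FPop	L	N	3	6.2	11.8	48	IA	Contralateral hemiparesis	6
5	F	35	22	13	Posterior insula + TPop	R	N	2.7	4.97	12.9	36	IIA	Contralateral hemihypesthesia	3
6	F	33	4	29	Superior insula + FPop	L	FCD	12	7	13.8	48	IA	Aphasia	4
7	F	35	21	14	Anterior insula + Fop	R	N	1.7	8.1	14.7	36	IA	None	NA
8	F	48	12	36	Superior insula + FPop	R	FCD	7.6	6.5	12.7	48	IA	None	NA
9	F	18	10	8	Anterior insula	L	N	10.2	5.7	11.7	24	IA	None	NA
10	F	22	10	12	Insula (subtotal) + FPop	R	N	6.8	5.4	10.4	24	IA	Contralateral hemiparesis	1
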