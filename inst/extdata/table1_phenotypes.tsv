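patient_id	diagnosis	age_at_diagnosis	sex	paraprotein	other_malignancies	family_history	pot1_carrier	in_cohort
79	MM	54	F	IgG kappa		brother: cancer NOS	no	yes
97	MM	56	M	IgG lambda			no	yes
40	MM	64	F	IgG kappa			no	yes
88	MM - PCL	54	M	IgG kappa			no	yes
53	MM	66	M	IgG kappa	prostate ca		no	yes
66	MM	73	F	kappa light chain			no	yes
78	MM	66	F	IgA lambda	basal-cell ca	father: gastric ca; sister: breast ca; brother: prostate ca	no	yes
91	sMM	61	F	IgA kappa		mother's mother: leukaemia NOS	no	yes
113	MM	50	M	IgA lambda	papillary thyroid ca	father: MM; sister: lung ca; paternal aunt: gastric ca	yes	yes
82	MM - t-MDS	66	M	IgG kappa	osteosarcoma; t-MDS	mother: AML	yes	yes
105	MM	55	F	kappa light chain		mother: MM; mother's father: MM; father: esophageal ca	yes	yes
35	MM	65	F	IgG kappa		father: gastric ca; sister: gastrointestinal ca	no	yes
FIN-1	MGUS	77	F		essential thrombocythemia; papillary thyroid ca	first-degree relative: cancer	yes	no
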