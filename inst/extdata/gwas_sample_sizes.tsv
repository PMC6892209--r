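trait	population	k_final	k_candidate	n_cases	n_controls	n_total	source
ALS	EUR	NA	NA	20806	59804	80610	AVS
T2D	EUR	67	139	62892	596424	659316	PCTG
BMI	EUR	91	95	NA	NA	339224	GIANT
FastingGlucose	EUR	35	35	NA	NA	133010	MAGIC
FastingInsulin	EUR	14	14	NA	NA	108557	MAGIC
HbA1c	EUR	36	37	NA	NA	123665	MAGIC
ALS	EAS	NA	NA	1234	2850	4084	Benyamin
T2D	EAS	34	72	36614	155150	191764	JENGER
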