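gene_id	label	family	evidence	e_value	conflict
ctg01_g0009	GH130	GH130	HMM+SEARCH	1.36017860339656e-09	FALSE
ctg01_g0010	GH26	GH26	HMM+SEARCH	3.65181413266348e-21	FALSE
ctg01_g0012	GH26	GH26	HMM+SEARCH	4.73503214559893e-15	FALSE
ctg01_g0013	GH27	GH27	HMM+SEARCH	6.30777387025394e-22	FALSE
ctg01_g0014	SUSC	SUSC	HMM	1.43796177456222e-23	FALSE
ctg01_g0015	SUSD	SUSD	HMM	4.52811300396694e-14	FALSE
ctg01_g0017	GH26	GH26	HMM+SEARCH	2.87892010874212e-26	FALSE
ctg01_g0018	GH5	GH5	HMM+SEARCH	4.41231890850508e-15	FALSE
ctg01_g0019	CE2	CE2	HMM+SEARCH	4.75578554577654e-28	FALSE
ctg01_g0030	SUSC	SUSC	HMM	2.51621245138468e-25	FALSE
ctg01_g0031	SUSD	SUSD	HMM	1.42133466216795e-27	FALSE
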