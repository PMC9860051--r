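ctg01_g0009	cazydb|GH130|80522	54.199	200	0	0	1	200	1	200	5.805e-77	500	84.586	GH130
ctg01_g0010	cazydb|GH26|37675	80.112	200	0	0	1	200	1	200	7.723e-67	500	82.286	GH26
ctg01_g0012	cazydb|GH26|02330	64.891	200	0	0	1	200	1	200	4.315e-70	500	73.151	GH26
ctg01_g0013	cazydb|GH27|60858	49.632	200	0	0	1	200	1	200	1.736e-66	500	78.125	GH27
ctg01_g0017	cazydb|GH26|36760	81.068	200	0	0	1	200	1	200	5.685e-36	500	80.018	GH26
ctg01_g0018	cazydb|GH5|44748	45.774	200	0	0	1	200	1	200	2.050e-58	500	67.235	GH5
ctg01_g0019	cazydb|CE2|15655	87.55	200	0	0	1	200	1	200	9.983e-42	500	81.185	CE2
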