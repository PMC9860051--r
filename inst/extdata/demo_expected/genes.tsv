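gene_id	contig_id	order_index	start	end	strand	locus_tag
ctg01_g0000	ctg01	0	1	901	-	CTG01_00000
ctg01_g0001	ctg01	1	1001	1901	+	CTG01_00005
ctg01_g0002	ctg01	2	2001	2901	+	CTG01_00010
ctg01_g0003	ctg01	3	3001	3901	+	CTG01_00015
ctg01_g0004	ctg01	4	4001	4901	-	CTG01_00020
ctg01_g0005	ctg01	5	5001	5901	-	CTG01_00025
ctg01_g0006	ctg01	6	6001	6901	+	CTG01_00030
ctg01_g0007	ctg01	7	7001	7901	+	CTG01_00035
ctg01_g0008	ctg01	8	8001	8901	+	CTG01_00040
ctg01_g0009	ctg01	9	9001	9901	+	CTG01_00045
ctg01_g0010	ctg01	10	10001	10901	+	CTG01_00050
ctg01_g0011	ctg01	11	11001	11901	-	CTG01_00055
ctg01_g0012	ctg01	12	12001	12901	+	CTG01_00060
ctg01_g0013	ctg01	13	13001	13901	+	CTG01_00065
ctg01_g0014	ctg01	14	14001	14901	+	CTG01_00070
ctg01_g0015	ctg01	15	15001	15901	+	CTG01_00075
ctg01_g0016	ctg01	16	16001	16901	+	CTG01_00080
ctg01_g0017	ctg01	17	17001	17901	+	CTG01_00085
ctg01_g0018	ctg01	18	18001	18901	+	CTG01_00090
ctg01_g0019	ctg01	19	19001	19901	+	CTG01_00095
ctg01_g0020	ctg01	20	20001	20901	+	CTG01_00100
ctg01_g0021	ctg01	21	21001	21901	+	CTG01_00105
ctg01_g0022	ctg01	22	22001	22901	-	CTG01_00110
ctg01_g0023	ctg01	23	23001	23901	+	CTG01_00115
ctg01_g0024	ctg01	24	24001	24901	+	CTG01_00120
ctg01_g0025	ctg01	25	25001	25901	-	CTG01_00125
ctg01_g0026	ctg01	26	26001	26901	-	CTG01_00130
ctg01_g0027	ctg01	27	27001	27901	-	CTG01_00135
ctg01_g0028	ctg01	28	28001	28901	+	CTG01_00140
ctg01_g0029	ctg01	29	29001	29901	-	CTG01_00145
ctg01_g0030	ctg01	30	30001	30901	+	CTG01_00150
ctg01_g0031	ctg01	31	31001	31901	+	CTG01_00155
ctg01_g0032	ctg01	32	32001	32901	-	CTG01_00160
ctg01_g0033	ctg01	33	33001	33901	+	CTG01_00165
ctg01_g0034	ctg01	34	34001	34901	-	CTG01_00170
ctg01_g0035	ctg01	35	35001	35901	-	CTG01_00175
ctg01_g0036	ctg01	36	36001	36901	-	CTG01_00180
ctg01_g0037	ctg01	37	37001	37901	-	CTG01_00185
ctg01_g0038	ctg01	38	38001	38901	+	CTG01_00190
ctg01_g0039	ctg01	39	39001	39901	-	CTG01_00195
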