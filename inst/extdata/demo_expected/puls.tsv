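contig_id	start_index	end_index	susc_id	susd_id	n_genes	n_cazymes	families	merged
ctg01	9	19	ctg01_g0014	ctg01_g0015	11	7	CE2,GH130,GH26,GH27,GH5	FALSE
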