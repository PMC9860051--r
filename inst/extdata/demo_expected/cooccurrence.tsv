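family	count	fraction	retained
CE2	1	1	TRUE
GH130	1	1	TRUE
GH26	1	1	TRUE
GH27	1	1	TRUE
GH5	1	1	TRUE
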