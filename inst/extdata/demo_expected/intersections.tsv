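family_set	count
CE2+GH130+GH26+GH27+GH5	1
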