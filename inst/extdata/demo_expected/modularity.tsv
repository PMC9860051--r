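pul	same_modularity
1	TRUE
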