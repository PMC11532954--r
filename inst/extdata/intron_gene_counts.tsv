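feature	genes_with_pg4	genes_total
intron	14610	19014
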