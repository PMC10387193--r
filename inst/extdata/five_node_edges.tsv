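gene_a	gene_b	weight
N1	N2	0.8
N1	N3	0.5
N2	N3	0.4
N3	N4	0.9
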