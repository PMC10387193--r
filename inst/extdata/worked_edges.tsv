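gene_a	gene_b	weight
G0001	G0002	0.3915336139068
G0001	G0005	0.1826688622885
G0001	G0019	0.0200000000000
G0002	G0004	0.3965562501257
G0003	G0005	0.1359040870627
G0004	G0009	0.0327613022178
G0006	G0007	0.1862082274165
G0006	G0009	0.1503642739961
G0007	G0008	0.1720924504800
G0008	G0009	0.1657515878091
G0008	G0019	0.0200000000000
G0011	G0013	0.2437204266433
G0011	G0015	0.2321633182000
G0013	G0014	0.2265437272377
G0013	G0015	0.1751801093807
G0016	G0018	0.1617555723293
G0017	G0019	0.1865872510243
G0018	G0020	0.1644773439504
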