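sample_id	label
S0001	0
S0002	1
S0003	1
S0004	0
S0005	1
S0006	1
S0007	0
S0008	0
S0009	0
S0010	1
S0011	0
S0012	0
S0013	0
S0014	0
S0015	1
S0016	1
S0017	0
S0018	0
S0019	0
S0020	0
S0021	0
S0022	0
S0023	1
S0024	0
S0025	0
S0026	1
S0027	0
S0028	0
S0029	1
S0030	0
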