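exposure	mediator	outcome	me	me_low	me_high	mp_pct	mp_low_pct	mp_high_pct	or_total
CD11c+ monocyte %monocyte	Adrenate (22:4n6) levels	Pancreatic cancer	-0.00837	-0.0183	0.00153	-8.39	-18.3	1.54	1.105
HLA DR+ CD4+ AC	Cortisone levels	Pancreatic cancer	-0.0223	-0.116	0.0712	-26.6	138	-84.8	0.920
HLA DR+ CD8br %T cell	Oxalate (ethanedioate) levels	Pancreatic cancer	-0.00655	-0.0508	0.0377	-11.6	-89.7	66.6	1.058
HLA DR+ CD8br %T cell	Mannose to trans-4-hydroxyproline ratio	Pancreatic cancer	-0.011	-0.0768	0.0548	-19.4	-136	96.8	1.058
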