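snp	effect_allele	stimulus	beta_bitter	se_bitter	variance_explained	n_discovery	f_stat
rs1726866	G	prop	0.965	0.032147	0.46	1757	901.1
rs10772420	A	quinine	0.337	0.034253	0.06	1757	96.8
rs2597979	G	caffeine	0.264	0.048199	0.02	1757	30.0
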