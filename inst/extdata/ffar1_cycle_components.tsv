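ligand	minus_dG_complex	dG_water	dG_restr_on	dG_bind	se_complex	se_water
R-AM-8596	-121.602	103.941	6.559	-11.102	0.524	0.254
S-AM-8596	-123.153	103.996	6.7	-12.457	0.310	0.213
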