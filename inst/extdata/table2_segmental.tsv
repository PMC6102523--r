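geneA	geneB	species	ks_mean	ks_sd	age_printed_mya	gwd_mya
AT1G70370	AT1G23760	arabidopsis	0.795	0.122	26.5	28-48
Brara.I00536	Brara.B03626	brassica	0.480	0.203	17.1	13-17
Brara.F02754	Brara.I00536	brassica	0.451	0.123	16.1
Brara.F02754	Brara.B03626	brassica	0.441	0.191	15.8
Brara.G02440	Brara.G02959	brassica	0.380	0.074	13.6
Glyma.06G013400	Glyma.11G119100	soybean	0.553	0.102	45.3	13,59
Glyma.06G013400	Glyma.12G044600	soybean	0.548	0.163	44.9
Glyma.12G217300	Glyma.13G283900	soybean	0.145	0.083	11.9
Glyma.02G034700	Glyma.01G030900	soybean	0.151	0.051	12.3
Glyma.06G081100	Glyma.04G079600	soybean	0.132	0.042	10.8
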