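gene_id	snp_id	a1	a2	weight
gene001	snp00001	A	G	1.0059142685728617
gene001	snp00004	A	G	-0.20644175601942155
gene002	snp00006	A	G	0.8541451236622736
gene002	snp00007	A	G	0.28084265325073365
gene003	snp00008	A	G	-0.20211893954891125
gene003	snp00009	A	G	-0.9088285511107368
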