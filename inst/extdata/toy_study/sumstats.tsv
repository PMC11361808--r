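snp	a1	a2	beta	se	n
snp00001	A	G	0.8591917999033981	0.06818879839557475	150
snp00002	A	G	0.1721512624414956	0.09681705517300454	150
snp00003	A	G	0.02906976956633945	0.09780328322755671	150
snp00004	A	G	-0.05338989007266281	0.09773491026424899	150
snp00005	A	G	-0.0946093973370687	0.09752662696076417	150
snp00006	A	G	-0.1974844722508562	0.09649411955264052	150
snp00007	A	G	-0.06010849435512724	0.09770889935321317	150
snp00008	A	G	0.05100614261496172	0.09774339726827702	150
snp00009	A	G	0.20098381766818793	0.0964459395396064	150
snp00010	A	G	0.12909283790627354	0.09726261433930292	150
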