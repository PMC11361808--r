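snp00001	snp00002	snp00003	snp00004
1	0.3399389910418324	0.01760984777858096	0.1311783778348175
0.3399389910418324	1	0.23816779712756164	0.15486151254921482
0.01760984777858096	0.23816779712756164	1	0.3327655409555892
0.1311783778348175	0.15486151254921482	0.3327655409555892	1
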