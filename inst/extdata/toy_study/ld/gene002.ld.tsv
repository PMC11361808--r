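snp00004	snp00005	snp00006	snp00007
1	0.466325173828677	0.20784741771740858	0.16157757759561037
0.466325173828677	1	0.3513521343897678	0.14972012233205195
0.20784741771740858	0.3513521343897678	1	0.3992896576423225
0.16157757759561037	0.14972012233205195	0.3992896576423225	1
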