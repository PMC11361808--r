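snp00007	snp00008	snp00009	snp00010
1	0.3202370435585418	0.23293495531207684	0.07206329067693533
0.3202370435585418	1	0.36250622864937554	0.1131999359220753
0.23293495531207684	0.36250622864937554	1	0.32176759222110163
0.07206329067693533	0.1131999359220753	0.32176759222110163	1
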