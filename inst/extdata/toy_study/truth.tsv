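gene_id	beta	causal
gene001	0.792836261698931	TRUE
gene002	0	FALSE
gene003	-0.16144625817883662	TRUE
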