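SNP	R2_PCT	F	N
rs715	0.91	67.31	7354
rs17279437	1.18	87.70	7354
rs11613331	1.45	107.93	7354
rs1600760	0.46	34.08	7354
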