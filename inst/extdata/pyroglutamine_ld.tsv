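snp_a	snp_b	r2
rs715	rs17279437	0
rs715	rs11613331	0
rs715	rs1600760	0
rs17279437	rs11613331	0
rs17279437	rs1600760	0
rs11613331	rs1600760	0
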