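sample	type	count	total	printed_pct	digits
N9	CIS_ONLY	1524	11608	13.13	2
N9	TRANS_ONLY	1699	11608	14.64	2
9N	CIS_ONLY	1490	11608	12.84	2
9N	TRANS_ONLY	1702	11608	14.66	2
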