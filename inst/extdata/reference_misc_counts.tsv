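label	count	total	printed_pct	digits
parent_biased_in_silico	5823	11608	50.2	1
wgd_affected_common	2202	6636	33	0
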