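name	value
hairpin_a	5.0
hairpin_c	0.3
bulge_a	3.8
bulge_c	0.3
internal_a	2.5
internal_c	0.3
multi_a	4.6
multi_b	0.4
multi_c	0.1
comp_bonus	-1.0
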