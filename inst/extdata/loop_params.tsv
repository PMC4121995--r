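param	value
hairpin_base	3.0
hairpin_per_nt	0.3
bulge_base	3.2
bulge_per_nt	0.3
internal_base	2.0
internal_per_nt	0.3
multi_base	3.4
multi_branch	0.4
multi_unpaired	0.3
max_loop	30
min_hairpin	3
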