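quantity	PeuC	PeuS	PprC	PprS	Total
total_as_events	17033	15125	14672	13310	26560
loci_with_as_events	6662	5850	6192	5765	8380
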