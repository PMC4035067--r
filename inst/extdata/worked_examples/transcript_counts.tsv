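quantity	value
transcripts_identified	36144
annotated_genes	45033
transcripts_pct_of_annotated	80.3
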