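quantity	value
Peu_up	471
Peu_down	413
Peu_total	884
Ppr_up	593
Ppr_down	267
Ppr_total	860
common	314
union	1430
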