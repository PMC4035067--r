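cluster	size
Peu-up-only	272
Ppr-up-only	394
Peu-down-only	298
Ppr-down-only	152
co-up	198
co-down	114
Peu-up/Ppr-down	1
Peu-down/Ppr-up	1
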