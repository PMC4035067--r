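type	PeuC	PeuS	PprC	PprS	Total
SE	13323	12130	11655	10749	20334
RI	2867	2195	2182	1776	4795
A5SS	274	294	282	269	529
A3SS	250	232	251	230	430
AFE	162	129	148	142	222
ALE	157	145	154	144	250
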