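library_id	matched_genes	matched_genes_pct	unique_aligned	unique_pct	non_unique	non_unique_pct	unaligned	unaligned_pct	total_clean_tags
PeuC	33528	74.5	22704962	82.4	229952	0.8	4621235	16.8	27556149
PeuS	32508	72.2	23375397	80.6	297806	1.0	5314269	18.4	28987472
PprC	32996	73.3	22298805	79.2	241822	0.9	5599162	19.9	28139789
PprS	33055	73.4	23027167	81.0	364836	1.3	5046367	17.7	28438370
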