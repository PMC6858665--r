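origin	total	lincRNA	intronic	annotated_within	annotated_overlap	te_lncRNA
polyA_minus	9487	9153	29	189	116	7520
polyA_plus	13822	11346	156	1201	1119	7792
total	23309	20499	185	1390	1235	15312
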