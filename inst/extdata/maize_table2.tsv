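superfamily	te_lnc_count	pct_of_te_lnc_bp	pct_of_genomic_te_bp
SINE	15	0.36	0.02
LINE/L1	151	1.28	0.96
LINE/RTE-BovB	8	0.05	0.14
LTR/Cassandra	47	0.23	0.10
LTR/Copia	3917	22.45	32.39
LTR/Gypsy	9566	61.53	59.64
DNA	28	0.28	0.03
DNA/CMC-EnSpm	579	3.97	3.33
DNA/hAT-Ac	234	2.03	0.73
DNA/hAT-Tag1	20	0.56	0.08
DNA/hAT-Tip100	32	0.34	0.14
DNA/MULE-MuDR	213	1.70	0.93
DNA/PIF-Harbinger	291	2.80	0.64
DNA/TcMar-Stowaway	35	0.41	0.08
RC/Helitron	162	1.79	0.78
Unclassified	14	0.21	0.02
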