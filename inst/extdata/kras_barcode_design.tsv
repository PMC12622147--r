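codon_index	wildtype_codon	allowed_codons
2	ACT	ACT,ACC
9	GTT	GTT,GTC
10	GGA	GGA,GGG
11	GCT	GCT,GCC
13	GGC	GGC,GGT
14	GTA	GTA,GTG
15	GGC	GGC,GGT
16	AAG	AAG,AAA
17	AGC	AGC,AGT
18	GCC	GCC,GCT
19	TTG	TTG,TTA
20	ACG	ACG,ACA
21	ATA	ATA,ATT,ATC
22	CAG	CAG,CAA
23	CTA	CTA,CTG
24	ATT	ATT,ATA,ATC
25	CAG	CAG,CAA
26	AAT	AAT,AAC
27	CAT	CAT,CAC
28	TTT	TTT,TTC
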