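# mitochar provisional avian CR motif library v1 (box/CSB consensi are synthetic placeholders; edit for your taxon)
name	pattern	max_mismatch	strand
TACAT	TACAT	0	forward
ATGTA	ATGTA	0	forward
F-box	ATGGCCTGAAGTAAGAACCA	1	forward
E-box	AGGGTCTGTGGCAGTTAAGC	1	forward
D-box	CCTGACCGAGGAACCAGGTG	1	forward
C-box	CATCGGACTGGCTTCTGGAC	1	forward
CSBa	TTTGACATCACGTTGTGCAA	1	forward
CSBb	AAACCTCCGCTACCAAGTGT	1	forward
CSB1	TTATGGCCTCAAACGAGGAA	1	forward
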