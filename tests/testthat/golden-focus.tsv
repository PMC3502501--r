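tag	x	y	direction
TACCGAGATG	9	0	up
AAAGGGTCCT	19	7	up
AATCTCTTAG	9	1	up
GCGGCTCTTG	6	0	up
TCCGCAGAAT	5	0	up
CTTAATTATT	14	36	down
CACAGCGCGA	4	0	up
GAGACTCAAT	5	1	up
ACGAACCGGT	3	0	up
ATGGCACGGT	6	2	up
TCAGGCATTG	1	7	down
AAAAGCATAG	4	1	up
TATTTGCAAA	4	1	up
TTCCCGTGTG	4	1	up
CCACGCGATT	5	14	down
CGCCTTCAGA	5	2	up
CTGGCGCAAA	5	2	up
ATCAAGGAGA	2	0	up
GTCCCAGAGG	0	4	down
CGCAAGGCCT	2	8	down
TGCAGTTCAA	6	3	up
ATGCCGCTCT	1	6	down
AGGGGCGCGG	3	1	up
ATCACGCGTT	3	1	up
CCCACCTGTA	3	1	up
GGCTGGGACG	3	1	up
AAAGTGTCAA	2	7	down
ATAAACGTTG	2	7	down
ACCAATCCGG	1	5	down
TGTCAGGTCG	1	5	down
TGTTCGTGCT	1	5	down
GTTCACATAG	0	3	down
GATCCCGTGG	1	0	up
ATGTGCAAAT	2	6	down
CAACCACCTT	2	6	down
CCGGCTCTAA	2	6	down
GATTTCCGCG	1	4	down
GTGCAAAAAG	1	4	down
GTGCGATCAT	1	4	down
TAGCGGACGA	1	4	down
TTGTCCCTTT	1	4	down
ATTGATTTCT	0	2	down
ATTTCTTACT	0	2	down
CTACGGTATA	0	2	down
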