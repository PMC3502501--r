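rop_count	c57_count	glom_gene	glom_logfc	glom_q	tub_gene	tub_logfc	tub_q
0	7	Slc22a6	-0.42	0.00	Slc22a6	-0.22	0.00
0	9	Slc4a4	-0.32	0.00	NA	NA	NA
1.35	13	Aqp1	-0.30	0.00	NA	NA	NA
5.4	0	Psmb5	0.21	0.00	NA	NA	NA
5.4	0	Pcbp1	0.24	0.00	NA	NA	NA
5.4	0	Psma3	0.31	0.00	NA	NA	NA
6.75	20	Pdzk1ip1	-0.15	0.02	NA	NA	NA
74.25	45	Igfbp7	0.14	0.02	NA	NA	NA
12.15	3	Mdh2	0.16	0.02	NA	NA	NA
9.45	0	Vamp8	0.11	0.03	NA	NA	NA
8.1	1	Tmbim4	0.12	0.03	NA	NA	NA
5.4	0	Ndufb11	0.21	0.03	NA	NA	NA
4.05	16	Lifr	-0.09	0.05	Lifr	-0.27	0.00
12.15	3	Sod1	0.06	0.09	NA	NA	NA
16.2	6	Herpud1	-0.07	0.14	NA	NA	NA
2.7	13	Atp6v1a	-0.03	0.15	NA	NA	NA
8.1	42	Nrp2b	-0.03	0.15	NA	NA	NA
2.7	12	NA	0.11	0.11	Id2	-0.40	0.00
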