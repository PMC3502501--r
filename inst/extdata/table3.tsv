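gene_symbol	rop_os	c57_os	p_value
Glud1	54	14	2.7461E-06
Pea15	15	0	0.000115878
Aspm	15	1	0.000577048
Hsp90ab1	0	14	0.001280824
Rpl23	14	39	0.0017137
Atpif1	19	4	0.002494576
Rpl37	19	4	0.002494576
Aqp1	1	13	0.007371123
Mdh1	36	66	0.008331722
Ndrg1	46	23	0.008962126
Atp6v1g1	7	0	0.009358827
Ctbp1	7	0	0.009358827
Nudt19	14	33	0.010481768
Cgnl1	1	12	0.011021395
Igfbp7	74	45	0.011671747
Cox6c	39	19	0.012221381
Cox4i1	26	10	0.012316032
Ddx5	27	11	0.013319653
Psap	53	30	0.018772506
Agps	5	0	0.020110086
Dpep1	5	0	0.020110086
Prdx6	5	0	0.020110086
Tmsb4x	5	0	0.020110086
Tufm	5	0	0.020110086
Uqcrh	5	0	0.020110086
Pdzk1ip1	7	20	0.022573009
Mdh2	12	3	0.022949534
Sod1	12	3	0.022949534
Id2	3	12	0.032439845
Sdf4	0	6	0.035034341
Tns1	14	14	0.037827945
Herpud1	16	6	0.038419946
Ttr	16	6	0.038419946
Prdx1	5	16	0.041379494
Calm2	11	3	0.042872521
Rps28	11	3	0.042872521
Slc25a3	14	28	0.042939254
Ankhd1	7	1	0.043285935
Fech	7	1	0.043521115
Tmem111	7	1	0.043285935
Gnb2	7	18	0.043285935
Abhd3	4	0	0.044128269
Acad9	4	0	0.044128269
Aig1	4	0	0.044128269
Atp6ap1	4	0	0.044128269
B3gat3	4	0	0.044128269
Cct4	4	0	0.044128269
Cited2	4	0	0.044128269
Creld1	4	0	0.044128269
Ctgf	4	0	0.044128269
Fads2	4	0	0.044128269
Fkbp2	4	0	0.044128269
HNMT	4	0	0.044128269
Itgb1	4	0	0.044128269
Kctd2	4	0	0.044128269
Mcl1	4	0	0.044128269
Mknk2	4	0	0.044128269
Mpdu1	4	0	0.044128269
Nucb1	4	0	0.044128269
Pmm1	4	0	0.044128269
Ptger4	4	0	0.044128269
Rab24	4	0	0.044128269
Sbf1	4	0	0.044128269
Scpep1	4	0	0.044128269
Sfrs6	4	0	0.044128269
Zdhhc8	4	0	0.044128269
Hspa5	3	11	0.047594628
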