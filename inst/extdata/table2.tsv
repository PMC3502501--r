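tag	rop_os	c57_os	p_value	gene_symbol	gene_name
CTATCCTCTC	873	613	1.47E-10	Gpx3	Glutathione peroxidase 3
ATTAACTTGG	54	14	75E-06	Glud1	Glutamate dehydrogenase 1
TGGTTGCTGG	8	42	2.53E-05	Nrp2b	Neuropilin2b
TCAAAAAAAA	15	0	0.000115878	Pea15	Phosphoprotein enriched in astrocytes 15
ACAAAAAAAA	20	2	0.000138392	Pde6c	Phosphodiesterase 6C, cGMP specific, cone, alpha prime
AACTTGATTA	14	0	0.000237608	Ndufa12	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex, 12
GTTCACTTTC	27	6	0.000390333	Atp5e	ATP synthase, H+ transporting, mitochondrial F1 complex, epsilon subunit
CTGCTGTAAT	15	2	0.000577048	Aspm	Asp (abnormal spindle)-like, microcephaly associated (Drosophila)
TGTTGTGTTT	0	15	0.000858214	Lman2l	Lectin, mannose-binding 2-like
GTGAGCCCAT	0	14	0.001280824	Hsp90ab1	Heat shock protein 90 kDa alpha (cytosolic), class B member 1
GCCACGCCCC	24	6	0.001296626	Hpd	4-hydroxyphenylpyruvic acid dioxygenase
ATTCTCCAGT	14	39	0.0017137	Rpl23	Ribosomal protein L32
GTCCTGAGAG	9	0	0.002106134	Vamp8	Vesicle-associated membrane protein 8
ATAAAAAAAA	9	0	0.002106134	Bag4	BCL2-associated athanogene 4
ATTCTAACAT	15	2	0.002151531	Acadm	Acyl-Coenzyme A dehydrogenase, medium chain
TGGATGCCTT	1	16	0.002228166	Adh1	Alcohol dehydrogenase
GATTCCGTGA	1	4	0.002494576	Rpl37	Ribosomal protein L37
GCTTTGAATG	19	4	0.002494576	Atpif1	ATPase inhibitory factor 1
TGTCATCTAG	6	30	0.000282	Rpsa	Ribosomal protein SA (laminin receptor like 1)
TGCTGCTCCC	0	12	0.00287027	Gyk	Glycerol kinase
GCTGGCCTCC	1	15	0.003314916	Rhoq	Ras homolog gene family, member Q
GCCAAGTGGA	22	6	0.0041826	Eef2	Eukaryotic translation elongation factor 2
GTTTGTAAAA	22	6	0.0041826	Acsm3	Acyl-CoA synthetase medium-chain family member 3
AGATAACACA	8	0	0.004417209	Rere (atrophin-2)	Arginine glutamic acid dipeptide (RE) repeats
AAGACCTATG	39	17	0.004902036	Dbi	Diazepam binding inhibitor
ATCCGATTCC	11	31	0.005368014	Miox	myo-inositol oxygenase
GTCAATGACG	1	13	0.007371123	Aqp1	Aquaporin1
TCAGGCTGCC	180	130	0.008291421	Fth1	Ferritin heavy chain1
TTGTTAGTGC	36	66	0.008331722	Mdh1	Malate dehydrogenase 1
CTAGTCTTTG	22	7	0.008750438	Rps29	Ribosomal protein S29
CTGCTGTGGA	22	7	0.008750438	Hmgcs2	3-hydroxy-3-methylglutaryl-Coenzyme A synthase 2
AGAGACAAGG	46	23	0.008962126	Ndrg1	N-myc downstream regulated gene 1
GATCAGAAAA	7	0	0.009358827	Prdm16	PR domain containing 16
GTGTGATACA	7	0	0.009358827	Pccb	propionyl Coenzyme A carboxylase, beta polypeptide
CAGTTGGTTC	7	0	0.009358827	Mm.399814	Transcribed locus
CAGTAAAAAA	7	0	0.009358827	Map3k7ip1	Mitogen-activated protein kinase kinasekinase 7interacting protein 1
AACTTTTAAA	7	0	0.009358827	Hp1bp3	Heterochromatin protein 1, binding protein 3
GCTGTATTCA	7	0	0.009358827	Folh1	Folate hydrolase
AATAAAAACT	7	0	0.009358827	FBXL12	F-box and leucine-rich repeat protein 12
TTTGTGACTG	7	0	0.009358827	Ctbp1	C-terminal binding protein 1
AGATCTGCCC	7	0	0.009358827	Atp6v1g1	ATPase, H+ transporting, lysosomal V1 subunit G1
CTGCGGGTCT	7	0	0.009358827	Angptl7	Angiopoietin-like 7
GACCGTCTCA	0	9	0.0098287	Slc4a4	Solute carrier family 4 (anion exchanger), member 4
TTGGACTGAG	0	9	0.0098287	Gabarapl2	Gamma-aminobutyric acid (GABA-A) receptorassociated protein-like 2
TGATTTTGAA	9	1	0.01011074	Por	P450 (cytochrome) oxidoreductase
GAGACTAGCA	3	15	0.010247643	Tspan3	Tetraspanin 3
GTCGTGCCAT	14	33	0.010481768	Nudt19	Nudix (nucleoside diphosphate linked moiety X)-typemotif 19
TGAGGGGAGC	1	12	0.011021395	Flrt2	Fibronectin leucine rich transmembraneprotein 2
TGCCCCCTCC	1	12	0.011021395	Cgnl1	Cingulin-like 1
TAGCTTTAAA	74	45	0.011671747	Igfbp7	Insulin-like growth factor binding protein 7
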