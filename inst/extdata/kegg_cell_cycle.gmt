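CELL_CYCLE_HS	KEGG-derived cell cycle gene symbols, human	CDK1	CDK2	CDK4	CDK6	CDK7	CCNA1	CCNA2	CCNB1	CCNB2	CCNB3	CCND1	CCND2	CCND3	CCNE1	CCNE2	CCNH	CDC6	CDC7	CDC14A	CDC14B	CDC16	CDC20	CDC23	CDC25A	CDC25B	CDC25C	CDC26	CDC27	CDC45	CDKN1A	CDKN1B	CDKN1C	CDKN2A	CDKN2B	CDKN2C	CDKN2D	ANAPC1	ANAPC2	ANAPC4	ANAPC5	ANAPC7	ANAPC10	ANAPC11	ANAPC13	MCM2	MCM3	MCM4	MCM5	MCM6	MCM7	ORC1	ORC2	ORC3	ORC4	ORC5	ORC6	E2F1	E2F2	E2F3	E2F4	E2F5	RB1	RBL1	RBL2	TP53	MDM2	GADD45A	GADD45B	GADD45G	ATM	ATR	CHEK1	CHEK2	WEE1	WEE2	PKMYT1	PLK1	BUB1	BUB1B	BUB3	MAD1L1	MAD2L1	MAD2L2	TTK	ESPL1	PTTG1	PTTG2	SMC1A	SMC1B	SMC3	STAG1	STAG2	RAD21	SKP1	SKP2	CUL1	RBX1	FZR1	HDAC1	HDAC2	TFDP1	TFDP2	TGFB1	TGFB2	TGFB3	SMAD2	SMAD3	SMAD4	MYC	ABL1	GSK3B	CREBBP	EP300	PCNA	PRKDC	RAD9A	HUS1	RAD1	RAD17	YWHAB	YWHAE	YWHAG	YWHAH	YWHAQ	YWHAZ	SFN	PLK2	PLK3	PLK4	AURKA	AURKB	NDC80	CENPE	KIF11	TOP2A	MKI67	FOXM1
CELL_CYCLE_MM	KEGG-derived cell cycle gene symbols, mouse	Cdk1	Cdk2	Cdk4	Cdk6	Cdk7	Ccna1	Ccna2	Ccnb1	Ccnb2	Ccnb3	Ccnd1	Ccnd2	Ccnd3	Ccne1	Ccne2	Ccnh	Cdc6	Cdc7	Cdc14a	Cdc14b	Cdc16	Cdc20	Cdc23	Cdc25a	Cdc25b	Cdc25c	Cdc26	Cdc27	Cdc45	Cdkn1a	Cdkn1b	Cdkn1c	Cdkn2a	Cdkn2b	Cdkn2c	Cdkn2d	Anapc1	Anapc2	Anapc4	Anapc5	Anapc7	Anapc10	Anapc11	Anapc13	Mcm2	Mcm3	Mcm4	Mcm5	Mcm6	Mcm7	Orc1	Orc2	Orc3	Orc4	Orc5	Orc6	E2f1	E2f2	E2f3	E2f4	E2f5	Rb1	Rbl1	Rbl2	Trp53	Mdm2	Gadd45a	Gadd45b	Gadd45g	Atm	Atr	Chek1	Chek2	Wee1	Wee2	Pkmyt1	Plk1	Bub1	Bub1b	Bub3	Mad1l1	Mad2l1	Mad2l2	Ttk	Espl1	Pttg1	Smc1a	Smc1b	Smc3	Stag1	Stag2	Rad21	Skp1	Skp2	Cul1	Rbx1	Fzr1	Hdac1	Hdac2	Tfdp1	Tfdp2	Tgfb1	Tgfb2	Tgfb3	Smad2	Smad3	Smad4	Myc	Abl1	Gsk3b	Crebbp	Ep300	Pcna	Prkdc	Rad9a	Hus1	Rad1	Rad17	Ywhab	Ywhae	Ywhag	Ywhah	Ywhaq	Ywhaz	Sfn	Plk2	Plk3	Plk4	Aurka	Aurkb	Ndc80	Cenpe	Kif11	Top2a	Mki67	Foxm1
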