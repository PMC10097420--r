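gene	chrom	dataset	direction	class	region	e16.placenta	e16.liver	e16.brain	P7.cortex	P7.hypothalamus	P7.cerebellum	P7.hippocampus	P7.brainstem	P60.cortex	P60.hypothalamus	P60.cerebellum	P60.hippocampus	P60.brainstem	strain_bias	reported_status
L3mbtl1	2	B	pat	1	.				48.1	53.4	53.4	46.4	50.1	49.4	49.7	46.7	51.0	49.2	TRUE	Biallelic
Ahi1	10	B,D	pat	1	.	52.8	46.5		47.0	51.6	50.9	52.8	46.9	48.6	49.4	50.0	52.4	51.3	TRUE	Biallelic
Platr20	11	A	pat	1	.	51.7	49.9	50.0	49.9	50.4	50.1	50.4	50.2	49.8	49.8	50.1	50.2	49.7	FALSE	Biallelic
Calm1	12	B,D	pat	1	.				54.7	49.5	51.4	45.9	43.4						TRUE	Biallelic
Nhlrc1	13	B,C,D	pat	1	.				56.6	55.6	57.8	54.8	58.8	58.1	56.1	55.4	55.0	55.2	TRUE	Paternal
Tnk1	11	A	mat	1	.														FALSE	Low expression
Mlana	18	B	mat	1	.														FALSE	Low expression
Gm16299	19	C	pat	1	.														FALSE	Low expression
Stx6	1	C	mat	2	.				50.7	49.2	50.3	49.8	50.1						FALSE	Biallelic
Gabra5	7	B,D	pat	2	.				51.5	53.2	52.5	54.8	52.6	52.3	50.7	48.6	51.5	51.5	FALSE	Biallelic
Wnk4	11	C	mat	2	.				50.1	52.0	45.3	50.6	44.0	48.1	44.6	50.9	45.4	48.1	TRUE	Maternal
Vat1	11	B	mat	2	.	43.9	50.9	52.6	49.6	48.8	50.4	51.0	49.9	46.4	51.3	50.8	49.8	50.4	TRUE	Placental
Rdm1	11	A	mat	2	.	49.4			48.8	48.8	50.1	50.2	50.7	46.9	49.5	50.5	50.1	48.7	TRUE	Biallelic
Gaa	11	B,D	pat	2	.	48.9	52.3	53.6	51.3	47.1	51.7	53.1	51.8	51.8	51.6	47.9	51.9	50.8	TRUE	Biallelic
Pcdhb10	18	D	mat	2	.														FALSE	Low expression
Pcdhb12	18	B,C	mat	2	.				40.5	41.2	41.0	39.4	41.8	42.6	42.7	42.1	43.2	44.9	FALSE	Maternal
Pcdhb20	18	B,C	pat	2	.			52.7	51.5	51.6	52.0	52.6	53.1	51.5	52.3	51.6	51.6	50.1	TRUE	Biallelic
Prdx5	19	B	pat	2	.	46.9	51.1	49.4	49.0	50.4	48.8	49.4	49.9	49.2	50.2	50.0	48.3	49.2	TRUE	Biallelic
Rtn3	19	D	pat	2	.	44.6	49.9	50.7	49.4	47.3	49.5	49.5	49.2	49.1	50.9	49.7	50.4	50.4	FALSE	Placental
Pla2g16	19	B	mat	2	.	40.3	51.6	50.6	51.7	49.7	48.9	48.5	50.7	51.5	51.2	49.2	46.8	48.3	TRUE	Placental
Mr1	1	C	mat	2	.														FALSE	Low expression
BC034090	1	C	mat	2	.														FALSE	Low expression
Tmem106a	11	A	mat	2	.														FALSE	Low expression
Adam23	1	A,B,C,D	pat	3	Zdbf2	48.0	52.0	59.1	56.5	57.8	56.5	58.0	53.7	55.6	58.7	53.5	56.5	54.1	FALSE	Paternal
Mcts2	2	A,B,C	pat	K	H13_Mcts2	77.2	82.9	64.7	71.8	80.2	73.1	77.3	80.4	85.7	78.3	70.6	87.8	84.2	FALSE	Paternal
Cox4i2	2	C	pat	3	H13_Mcts2	49.3			69.8	51.0	56.6	60.0	56.5	55.3	55.0	52.8	56.8	54.9	FALSE	Paternal
Bcl2l1	2	A,B,C,D	pat	3	H13_Mcts2	49.5	50.2	61.6	60.9	61.8	58.3	59.5	58.8	59.9	61.4	57.4	59.2	59.0	FALSE	Paternal
Tpx2	2	C	pat	3	H13_Mcts2		49.7	49.1	53.4	52.6	50.7	53.6	51.4	56.4	55.4	64.6	62.5	61.1	TRUE	Paternal
Herc3	6	A,B,C,D	mat	K	Herc3_Nap1l5	47.0	45.8	43.1	45.7	40.7	40.5	49.9	32.4	44.0	29.5	39.0	42.3	24.4	TRUE	Maternal
Fam13a	6	B,D	mat	3	Herc3_Nap1l5		46.1	53.2	47.9	47.1	51.3	49.4	48.4						TRUE	Biallelic
Zfp78	7	B	both	3	Peg3														FALSE	Low expression
Smim17	7	B,D	mat	3	Peg3			38.3	48.8	35.5	50.9	44.0	44.5	45.2	43.2	52.1	50.8	49.3	FALSE	Maternal
Peg3	7	A,B,C,D	pat	K	Peg3	96.3	99.2	99.6	92.4	92.8	94.1	94.3	95.1	97.5	98.0	98.0	97.3	97.7	TRUE	Paternal
Zfp954	7	B	mat	3	Peg3														FALSE	Low expression
Zfp773	7	B	mat	3	Peg3														FALSE	Low expression
Zfp772	7	B	mat	3	Peg3														FALSE	Low expression
Clcn4-2	7	B	mat	3	KvDMR	44.6	54.5	48.5	48.9	48.8	49.9	49.1	48.0	49.5	50.7	51.0	49.6	50.7	TRUE	Placental
Ifitm10	7	C,D	mat	3	KvDMR	46.9	52.3	48.7	47.5	41.5	53.0	49.4	45.0	49.0	43.2	43.6	50.7	47.0	TRUE	Maternal
Ctsd	7	B,D	mat	3	KvDMR	46.8	47.8	50.1	50.0	49.0	48.4	48.9	49.8	49.3	50.2	49.0	50.5	49.5	FALSE	Biallelic
Evl	12	B	pat	3	Dlk1_Dio3	46.2	48.3	50.2	48.7	51.3	51.1	50.2	49.5	50.9	50.9	52.6	50.8	50.6	TRUE	Biallelic
Slc25a29	12	B	pat	3	Dlk1_Dio3	18.9	45.5	52.3	53.9	56.2	54.5	53.3	54.2	52.8	53.8	50.6	53.6	53.2	TRUE	Placental
Wars	12	C	pat	3	Dlk1_Dio3	45.2	52.5	55.1	53.9	56.2	54.5	53.3	54.2	52.8	53.9	50.6	53.6	53.2	FALSE	Paternal
Wdr25	12	B,D	pat	3	Dlk1_Dio3				50.7	52.9	52.0	50.6	48.7	51.8	59.8	49.9	51.7		TRUE	Paternal
Dlk1	12	A,B,C,D	pat	K	Dlk1_Dio3	95.7	87.9	93.7	92.5	92.7	94.6	90.2	95.0	89.5	95.6	93.2	86.9	95.2	FALSE	Paternal
Ppp2r5c	12	B,C	pat	3	Dlk1_Dio3	52.4	51.3	48.5	48.6	49.3	54.0	50.6	48.2	50.6	48.7	45.2	51.0	49.3	TRUE	Biallelic
Dync1h1	12	B,C	pat	3	Dlk1_Dio3	46.9	49.8	50.4	50.7	50.7	51.1	49.9	50.4	51.0	50.4	50.1	50.1	49.8	FALSE	Biallelic
Ago2	15	A,B,C,D	mat	3	Trappc9_Peg13	47.7	50.7	30.1	24.1	25.8	28.8	28.7	19.3	25.9	28.7	38.0	33.3	24.6	FALSE	Maternal
Ampd3	7	B	mat	K	KvDMR	23.4	47.5	51.4	48.6	48.5	48.3	51.8	50.9	50.1	46.7	50.9	49.4	51.5	TRUE	Placental
Gab1	8	A	pat	K	Gab1	74.9	50.4	49.8	52.7	49.6	48.6	49.4	51.0	47.1	49.6	48.8	50.1	50.2	FALSE	Placental
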