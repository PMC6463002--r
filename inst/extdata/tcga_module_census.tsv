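module	genes	events	AA	AD	AT	ES	ME	RI
BLCA_M1	302	332	22	19	130	73	0	88
BLCA_M2	188	191	4	0	152	30	1	4
BLCA_M3	118	119	8	7	91	12	0	1
BLCA_M4	104	111	3	4	73	26	1	4
BRCA_M1	239	257	14	8	137	73	1	24
BRCA_M2	216	221	8	8	158	37	2	8
BRCA_M3	107	121	6	5	54	40	1	15
BRCA_M4	51	52	2	2	25	19	1	3
COAD_M1	91	94	2	0	67	15	0	10
COAD_M2	57	66	2	1	48	8	1	6
COAD_M3	56	56	1	4	49	1	0	1
COAD_M4	42	43	2	3	16	6	0	16
ESCA_M1	132	141	5	13	60	32	0	31
ESCA_M2	86	87	1	8	64	12	1	1
HNSC_M1	200	220	14	9	93	53	1	50
HNSC_M2	159	165	3	4	126	28	0	4
HNSC_M3	116	127	7	2	84	29	0	5
KICH_M1	449	490	23	23	224	125	1	94
KICH_M2	363	383	10	19	232	90	5	27
KICH_M3	272	290	7	17	164	78	2	22
KIRC_M1	630	710	41	36	229	210	3	191
KIRC_M2	279	286	1	3	243	30	5	4
KIRC_M3	104	137	8	5	80	38	2	4
KIRP_M1	442	483	34	29	189	110	0	121
KIRP_M2	283	324	6	8	262	33	2	13
LIHC_M1	163	169	5	7	105	28	1	23
LIHC_M2	148	154	6	4	118	21	0	5
LIHC_M3	49	53	2	4	30	8	0	9
LIHC_M4	42	43	2	1	36	3	0	1
LUAD_M1	305	321	11	4	212	79	4	11
LUAD_M2	217	230	13	21	71	64	0	61
LUAD_M3	192	196	7	7	132	42	3	5
LUSC_M1	526	574	16	16	312	208	5	17
LUSC_M2	397	428	20	38	235	113	6	16
LUSC_M3	281	333	19	24	128	81	1	80
PRAD_M1	202	220	11	9	82	51	0	67
PRAD_M2	105	105	1	1	80	19	0	4
PRAD_M3	8	11	0	0	11	0	0	0
READ_M1	186	199	11	17	106	31	1	33
READ_M2	132	154	10	7	66	29	1	41
READ_M3	122	131	3	1	67	52	0	8
STAD_M1	141	164	11	13	37	41	0	62
STAD_M2	123	130	9	10	51	51	2	7
STAD_M3	108	112	1	3	71	35	1	1
STAD_M4	34	34	0	0	25	8	0	1
STAD_M5	17	24	1	1	16	4	0	2
THCA_M1	157	168	0	2	128	22	0	16
THCA_M2	149	151	4	2	114	17	0	14
UCEC_M1	292	302	7	5	244	31	2	13
UCEC_M2	206	210	4	4	172	14	0	16
UCEC_M3	117	121	4	7	65	27	1	17
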