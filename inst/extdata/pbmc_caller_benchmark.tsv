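dataset	tool	combination	TP	FP	TN	FN	sensitivity	specificity	f1
cell_hashing	DoubletDecon	single	759	1169	5364	1110	40.61	82.11	0.40
cell_hashing	DoubletFinder	single	570	559	5974	1299	30.5	91.44	0.38
cell_hashing	Scrublet	single	487	345	6188	1382	26.06	94.72	0.36
cell_hashing	DoubletDecon+DoubletFinder	union	1057	1506	5027	812	56.55	76.95	0.48
cell_hashing	DoubletFinder+Scrublet	union	782	731	5802	1087	41.84	88.81	0.46
cell_hashing	DoubletDecon+Scrublet	union	946	1327	5206	923	50.62	79.69	0.46
cell_hashing	All_three	union	1140	1592	4941	729	61	75.63	0.50
cell_hashing	DoubletDecon+DoubletFinder	intersection	272	222	6311	1597	14.55	96.6	0.23
cell_hashing	DoubletFinder+Scrublet	intersection	275	173	6360	1594	14.71	97.35	0.24
cell_hashing	DoubletDecon+Scrublet	intersection	300	187	6346	1569	16.05	97.14	0.26
cell_hashing	All_three	intersection	171	101	6432	1698	9.15	98.45	0.16
cell_hashing	DoubletDecon	consensus_20_runs	510	705	5828	1359	27.29	89.21	0.33
demuxlet	DoubletDecon	single	849	1003	4096	577	59.54	80.33	0.52
demuxlet	DoubletFinder	single	290	327	4772	1136	20.34	93.59	0.28
demuxlet	Scrublet	single	439	306	4793	987	30.79	94	0.40
demuxlet	DoubletDecon+DoubletFinder	union	921	1192	3907	505	64.59	76.62	0.52
demuxlet	DoubletFinder+Scrublet	union	509	509	4590	917	35.69	90.02	0.42
demuxlet	DoubletDecon+Scrublet	union	917	1121	3978	509	64.31	78.02	0.53
demuxlet	All_three	union	949	1265	3834	477	66.55	75.19	0.52
demuxlet	DoubletDecon+DoubletFinder	intersection	218	138	4961	1208	15.29	97.29	0.24
demuxlet	DoubletFinder+Scrublet	intersection	220	124	4975	1206	15.43	97.57	0.25
demuxlet	DoubletDecon+Scrublet	intersection	371	188	4911	1055	26.02	96.31	0.37
demuxlet	All_three	intersection	180	79	5020	1246	12.62	98.45	0.21
demuxlet	DoubletDecon	consensus_20_runs	664	629	4470	763	46.53	87.66	0.49
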