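name	species	locus	segment_class	ordinal	orientation	cluster	rss_5p	rss_3p	functionality
TRAV1-1	human	TRA	V	1	forward	none	none	spacer23	functional
TRAV1-2	human	TRA	V	2	forward	none	none	spacer23	functional
TRAV2	human	TRA	V	3	forward	none	none	spacer23	functional
TRAV3	human	TRA	V	4	forward	none	none	spacer23	functional
TRAV4	human	TRA	V	5	forward	none	none	spacer23	functional
TRAV5	human	TRA	V	6	forward	none	none	spacer23	functional
TRAV6	human	TRA	V	7	forward	none	none	spacer23	functional
TRAV7	human	TRA	V	8	forward	none	none	spacer23	functional
TRAV8-1	human	TRA	V	9	forward	none	none	spacer23	functional
TRAV9-1	human	TRA	V	10	forward	none	none	spacer23	functional
TRAV10	human	TRA	V	11	forward	none	none	spacer23	functional
TRAV11	human	TRA	V	12	forward	none	none	spacer23	pseudogene
TRAV12-1	human	TRA	V	13	forward	none	none	spacer23	functional
TRAV8-2	human	TRA	V	14	forward	none	none	spacer23	functional
TRAV8-3	human	TRA	V	15	forward	none	none	spacer23	functional
TRAV13-1	human	TRA	V	16	forward	none	none	spacer23	functional
TRAV12-2	human	TRA	V	17	forward	none	none	spacer23	functional
TRAV8-4	human	TRA	V	18	forward	none	none	spacer23	functional
TRAV8-5	human	TRA	V	19	forward	none	none	spacer23	pseudogene
TRAV13-2	human	TRA	V	20	forward	none	none	spacer23	functional
TRAV14	human	TRA	V	21	forward	none	none	spacer23	functional
TRAV9-2	human	TRA	V	22	forward	none	none	spacer23	functional
TRAV15	human	TRA	V	23	forward	none	none	spacer23	pseudogene
TRAV12-3	human	TRA	V	24	forward	none	none	spacer23	functional
TRAV8-6	human	TRA	V	25	forward	none	none	spacer23	functional
TRAV16	human	TRA	V	26	forward	none	none	spacer23	functional
TRAV17	human	TRA	V	27	forward	none	none	spacer23	functional
TRAV18	human	TRA	V	28	forward	none	none	spacer23	functional
TRAV19	human	TRA	V	29	forward	none	none	spacer23	functional
TRAV20	human	TRA	V	30	forward	none	none	spacer23	functional
TRAV21	human	TRA	V	31	forward	none	none	spacer23	functional
TRAV22	human	TRA	V	32	forward	none	none	spacer23	functional
TRAV23	human	TRA	V	33	forward	none	none	spacer23	functional
TRAV24	human	TRA	V	34	forward	none	none	spacer23	functional
TRAV25	human	TRA	V	35	forward	none	none	spacer23	functional
TRAV26-1	human	TRA	V	36	forward	none	none	spacer23	functional
TRAV8-7	human	TRA	V	37	forward	none	none	spacer23	pseudogene
TRAV27	human	TRA	V	38	forward	none	none	spacer23	functional
TRAV28	human	TRA	V	39	forward	none	none	spacer23	pseudogene
TRAV29	human	TRA	V	40	forward	none	none	spacer23	functional
TRAV30	human	TRA	V	41	forward	none	none	spacer23	functional
TRAV31	human	TRA	V	42	forward	none	none	spacer23	pseudogene
TRAV32	human	TRA	V	43	forward	none	none	spacer23	pseudogene
TRAV33	human	TRA	V	44	forward	none	none	spacer23	pseudogene
TRAV26-2	human	TRA	V	45	forward	none	none	spacer23	functional
TRAV34	human	TRA	V	46	forward	none	none	spacer23	functional
TRAV35	human	TRA	V	47	forward	none	none	spacer23	functional
TRAV36	human	TRA	V	48	forward	none	none	spacer23	functional
TRAV37	human	TRA	V	49	forward	none	none	spacer23	pseudogene
TRAV38-1	human	TRA	V	50	forward	none	none	spacer23	functional
TRAV38-2	human	TRA	V	51	forward	none	none	spacer23	functional
TRAV39	human	TRA	V	52	forward	none	none	spacer23	functional
TRAV40	human	TRA	V	53	forward	none	none	spacer23	functional
TRAV41	human	TRA	V	54	forward	none	none	spacer23	functional
TRAJ61	human	TRA	J	55	forward	none	spacer12	none	pseudogene
TRAJ60	human	TRA	J	56	forward	none	spacer12	none	pseudogene
TRAJ59	human	TRA	J	57	forward	none	spacer12	none	ORF
TRAJ58	human	TRA	J	58	forward	none	spacer12	none	ORF
TRAJ57	human	TRA	J	59	forward	none	spacer12	none	functional
TRAJ56	human	TRA	J	60	forward	none	spacer12	none	functional
TRAJ55	human	TRA	J	61	forward	none	spacer12	none	pseudogene
TRAJ54	human	TRA	J	62	forward	none	spacer12	none	functional
TRAJ53	human	TRA	J	63	forward	none	spacer12	none	functional
TRAJ52	human	TRA	J	64	forward	none	spacer12	none	functional
TRAJ51	human	TRA	J	65	forward	none	spacer12	none	ORF
TRAJ50	human	TRA	J	66	forward	none	spacer12	none	functional
TRAJ49	human	TRA	J	67	forward	none	spacer12	none	functional
TRAJ48	human	TRA	J	68	forward	none	spacer12	none	functional
TRAJ47	human	TRA	J	69	forward	none	spacer12	none	functional
TRAJ46	human	TRA	J	70	forward	none	spacer12	none	functional
TRAJ45	human	TRA	J	71	forward	none	spacer12	none	functional
TRAJ44	human	TRA	J	72	forward	none	spacer12	none	functional
TRAJ43	human	TRA	J	73	forward	none	spacer12	none	functional
TRAJ42	human	TRA	J	74	forward	none	spacer12	none	functional
TRAJ41	human	TRA	J	75	forward	none	spacer12	none	functional
TRAJ40	human	TRA	J	76	forward	none	spacer12	none	functional
TRAJ39	human	TRA	J	77	forward	none	spacer12	none	functional
TRAJ38	human	TRA	J	78	forward	none	spacer12	none	functional
TRAJ37	human	TRA	J	79	forward	none	spacer12	none	functional
TRAJ36	human	TRA	J	80	forward	none	spacer12	none	functional
TRAJ35	human	TRA	J	81	forward	none	spacer12	none	pseudogene
TRAJ34	human	TRA	J	82	forward	none	spacer12	none	functional
TRAJ33	human	TRA	J	83	forward	none	spacer12	none	functional
TRAJ32	human	TRA	J	84	forward	none	spacer12	none	functional
TRAJ31	human	TRA	J	85	forward	none	spacer12	none	functional
TRAJ30	human	TRA	J	86	forward	none	spacer12	none	functional
TRAJ29	human	TRA	J	87	forward	none	spacer12	none	functional
TRAJ28	human	TRA	J	88	forward	none	spacer12	none	functional
TRAJ27	human	TRA	J	89	forward	none	spacer12	none	functional
TRAJ26	human	TRA	J	90	forward	none	spacer12	none	functional
TRAJ25	human	TRA	J	91	forward	none	spacer12	none	ORF
TRAJ24	human	TRA	J	92	forward	none	spacer12	none	functional
TRAJ23	human	TRA	J	93	forward	none	spacer12	none	functional
TRAJ22	human	TRA	J	94	forward	none	spacer12	none	functional
TRAJ21	human	TRA	J	95	forward	none	spacer12	none	functional
TRAJ20	human	TRA	J	96	forward	none	spacer12	none	functional
TRAJ19	human	TRA	J	97	forward	none	spacer12	none	ORF
TRAJ18	human	TRA	J	98	forward	none	spacer12	none	functional
TRAJ17	human	TRA	J	99	forward	none	spacer12	none	functional
TRAJ16	human	TRA	J	100	forward	none	spacer12	none	functional
TRAJ15	human	TRA	J	101	forward	none	spacer12	none	functional
TRAJ14	human	TRA	J	102	forward	none	spacer12	none	functional
TRAJ13	human	TRA	J	103	forward	none	spacer12	none	functional
TRAJ12	human	TRA	J	104	forward	none	spacer12	none	functional
TRAJ11	human	TRA	J	105	forward	none	spacer12	none	functional
TRAJ10	human	TRA	J	106	forward	none	spacer12	none	functional
TRAJ9	human	TRA	J	107	forward	none	spacer12	none	functional
TRAJ8	human	TRA	J	108	forward	none	spacer12	none	functional
TRAJ7	human	TRA	J	109	forward	none	spacer12	none	functional
TRAJ6	human	TRA	J	110	forward	none	spacer12	none	functional
TRAJ5	human	TRA	J	111	forward	none	spacer12	none	functional
TRAJ4	human	TRA	J	112	forward	none	spacer12	none	functional
TRAJ3	human	TRA	J	113	forward	none	spacer12	none	functional
TRAJ2	human	TRA	J	114	forward	none	spacer12	none	pseudogene
TRAJ1	human	TRA	J	115	forward	none	spacer12	none	pseudogene
TRAC	human	TRA	C	116	forward	none	none	none	functional
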