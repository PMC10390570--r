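name	species	locus	segment_class	ordinal	orientation	cluster	rss_5p	rss_3p	functionality
TRAV1	mouse	TRA	V	1	forward	none	none	spacer23	functional
TRAV2	mouse	TRA	V	2	forward	none	none	spacer23	functional
TRAV3-1	mouse	TRA	V	3	forward	none	none	spacer23	functional
TRAV3-3	mouse	TRA	V	4	forward	none	none	spacer23	functional
TRAV3-4	mouse	TRA	V	5	forward	none	none	spacer23	functional
TRAV4-2	mouse	TRA	V	6	forward	none	none	spacer23	functional
TRAV4-3	mouse	TRA	V	7	forward	none	none	spacer23	functional
TRAV4-4	mouse	TRA	V	8	forward	none	none	spacer23	functional
TRAV5-1	mouse	TRA	V	9	forward	none	none	spacer23	functional
TRAV5-2	mouse	TRA	V	10	forward	none	none	spacer23	functional
TRAV5-4	mouse	TRA	V	11	forward	none	none	spacer23	functional
TRAV6-1	mouse	TRA	V	12	forward	none	none	spacer23	functional
TRAV6-2	mouse	TRA	V	13	forward	none	none	spacer23	functional
TRAV6-3	mouse	TRA	V	14	forward	none	none	spacer23	functional
TRAV6-4	mouse	TRA	V	15	forward	none	none	spacer23	functional
TRAV6-5	mouse	TRA	V	16	forward	none	none	spacer23	functional
TRAV6-6	mouse	TRA	V	17	forward	none	none	spacer23	functional
TRAV6-7	mouse	TRA	V	18	forward	none	none	spacer23	functional
TRAV7-1	mouse	TRA	V	19	forward	none	none	spacer23	functional
TRAV7-2	mouse	TRA	V	20	forward	none	none	spacer23	functional
TRAV7-3	mouse	TRA	V	21	forward	none	none	spacer23	functional
TRAV7-4	mouse	TRA	V	22	forward	none	none	spacer23	functional
TRAV7-5	mouse	TRA	V	23	forward	none	none	spacer23	functional
TRAV7-6	mouse	TRA	V	24	forward	none	none	spacer23	functional
TRAV8-1	mouse	TRA	V	25	forward	none	none	spacer23	functional
TRAV8-2	mouse	TRA	V	26	forward	none	none	spacer23	functional
TRAV9-1	mouse	TRA	V	27	forward	none	none	spacer23	functional
TRAV9-2	mouse	TRA	V	28	forward	none	none	spacer23	functional
TRAV9-3	mouse	TRA	V	29	forward	none	none	spacer23	functional
TRAV9-4	mouse	TRA	V	30	forward	none	none	spacer23	functional
TRAV10	mouse	TRA	V	31	forward	none	none	spacer23	functional
TRAV11	mouse	TRA	V	32	forward	none	none	spacer23	pseudogene
TRAV12-1	mouse	TRA	V	33	forward	none	none	spacer23	functional
TRAV12-2	mouse	TRA	V	34	forward	none	none	spacer23	functional
TRAV12-3	mouse	TRA	V	35	forward	none	none	spacer23	functional
TRAV13-1	mouse	TRA	V	36	forward	none	none	spacer23	functional
TRAV13-2	mouse	TRA	V	37	forward	none	none	spacer23	functional
TRAV13-3	mouse	TRA	V	38	forward	none	none	spacer23	functional
TRAV13-4	mouse	TRA	V	39	forward	none	none	spacer23	ORF
TRAV13-5	mouse	TRA	V	40	forward	none	none	spacer23	pseudogene
TRAV14-1	mouse	TRA	V	41	forward	none	none	spacer23	functional
TRAV14-2	mouse	TRA	V	42	forward	none	none	spacer23	functional
TRAV14-3	mouse	TRA	V	43	forward	none	none	spacer23	functional
TRAV15-1	mouse	TRA	V	44	forward	none	none	spacer23	pseudogene
TRAV15-2	mouse	TRA	V	45	forward	none	none	spacer23	functional
TRAV16	mouse	TRA	V	46	forward	none	none	spacer23	functional
TRAV17	mouse	TRA	V	47	forward	none	none	spacer23	functional
TRAV18	mouse	TRA	V	48	forward	none	none	spacer23	pseudogene
TRAV19	mouse	TRA	V	49	forward	none	none	spacer23	functional
TRAV20	mouse	TRA	V	50	forward	none	none	spacer23	functional
TRAV21	mouse	TRA	V	51	forward	none	none	spacer23	functional
TRAJ61	mouse	TRA	J	52	forward	none	spacer12	none	pseudogene
TRAJ60	mouse	TRA	J	53	forward	none	spacer12	none	pseudogene
TRAJ59	mouse	TRA	J	54	forward	none	spacer12	none	pseudogene
TRAJ58	mouse	TRA	J	55	forward	none	spacer12	none	functional
TRAJ57	mouse	TRA	J	56	forward	none	spacer12	none	functional
TRAJ56	mouse	TRA	J	57	forward	none	spacer12	none	functional
TRAJ55	mouse	TRA	J	58	forward	none	spacer12	none	pseudogene
TRAJ54	mouse	TRA	J	59	forward	none	spacer12	none	functional
TRAJ53	mouse	TRA	J	60	forward	none	spacer12	none	functional
TRAJ52	mouse	TRA	J	61	forward	none	spacer12	none	functional
TRAJ51	mouse	TRA	J	62	forward	none	spacer12	none	pseudogene
TRAJ50	mouse	TRA	J	63	forward	none	spacer12	none	functional
TRAJ49	mouse	TRA	J	64	forward	none	spacer12	none	functional
TRAJ48	mouse	TRA	J	65	forward	none	spacer12	none	functional
TRAJ47	mouse	TRA	J	66	forward	none	spacer12	none	ORF
TRAJ46	mouse	TRA	J	67	forward	none	spacer12	none	functional
TRAJ45	mouse	TRA	J	68	forward	none	spacer12	none	functional
TRAJ44	mouse	TRA	J	69	forward	none	spacer12	none	ORF
TRAJ43	mouse	TRA	J	70	forward	none	spacer12	none	functional
TRAJ42	mouse	TRA	J	71	forward	none	spacer12	none	functional
TRAJ41	mouse	TRA	J	72	forward	none	spacer12	none	pseudogene
TRAJ40	mouse	TRA	J	73	forward	none	spacer12	none	functional
TRAJ39	mouse	TRA	J	74	forward	none	spacer12	none	functional
TRAJ38	mouse	TRA	J	75	forward	none	spacer12	none	functional
TRAJ37	mouse	TRA	J	76	forward	none	spacer12	none	functional
TRAJ36	mouse	TRA	J	77	forward	none	spacer12	none	pseudogene
TRAJ35	mouse	TRA	J	78	forward	none	spacer12	none	functional
TRAJ34	mouse	TRA	J	79	forward	none	spacer12	none	functional
TRAJ33	mouse	TRA	J	80	forward	none	spacer12	none	functional
TRAJ32	mouse	TRA	J	81	forward	none	spacer12	none	functional
TRAJ31	mouse	TRA	J	82	forward	none	spacer12	none	functional
TRAJ30	mouse	TRA	J	83	forward	none	spacer12	none	functional
TRAJ29	mouse	TRA	J	84	forward	none	spacer12	none	pseudogene
TRAJ28	mouse	TRA	J	85	forward	none	spacer12	none	functional
TRAJ27	mouse	TRA	J	86	forward	none	spacer12	none	functional
TRAJ26	mouse	TRA	J	87	forward	none	spacer12	none	functional
TRAJ25	mouse	TRA	J	88	forward	none	spacer12	none	pseudogene
TRAJ24	mouse	TRA	J	89	forward	none	spacer12	none	functional
TRAJ23	mouse	TRA	J	90	forward	none	spacer12	none	functional
TRAJ22	mouse	TRA	J	91	forward	none	spacer12	none	functional
TRAJ21	mouse	TRA	J	92	forward	none	spacer12	none	functional
TRAJ20	mouse	TRA	J	93	forward	none	spacer12	none	pseudogene
TRAJ19	mouse	TRA	J	94	forward	none	spacer12	none	pseudogene
TRAJ18	mouse	TRA	J	95	forward	none	spacer12	none	functional
TRAJ17	mouse	TRA	J	96	forward	none	spacer12	none	functional
TRAJ16	mouse	TRA	J	97	forward	none	spacer12	none	functional
TRAJ15	mouse	TRA	J	98	forward	none	spacer12	none	functional
TRAJ14	mouse	TRA	J	99	forward	none	spacer12	none	pseudogene
TRAJ13	mouse	TRA	J	100	forward	none	spacer12	none	functional
TRAJ12	mouse	TRA	J	101	forward	none	spacer12	none	functional
TRAJ11	mouse	TRA	J	102	forward	none	spacer12	none	functional
TRAJ10	mouse	TRA	J	103	forward	none	spacer12	none	functional
TRAJ9	mouse	TRA	J	104	forward	none	spacer12	none	functional
TRAJ8	mouse	TRA	J	105	forward	none	spacer12	none	pseudogene
TRAJ7	mouse	TRA	J	106	forward	none	spacer12	none	pseudogene
TRAJ6	mouse	TRA	J	107	forward	none	spacer12	none	functional
TRAJ5	mouse	TRA	J	108	forward	none	spacer12	none	functional
TRAJ4	mouse	TRA	J	109	forward	none	spacer12	none	functional
TRAJ3	mouse	TRA	J	110	forward	none	spacer12	none	pseudogene
TRAJ2	mouse	TRA	J	111	forward	none	spacer12	none	functional
TRAJ1	mouse	TRA	J	112	forward	none	spacer12	none	pseudogene
TRAC	mouse	TRA	C	113	forward	none	none	none	functional
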