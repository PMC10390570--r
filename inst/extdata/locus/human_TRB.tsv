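name	species	locus	segment_class	ordinal	orientation	cluster	rss_5p	rss_3p	functionality
TRBV1	human	TRB	V	1	forward	none	none	spacer23	pseudogene
TRBV2	human	TRB	V	2	forward	none	none	spacer23	functional
TRBV3-1	human	TRB	V	3	forward	none	none	spacer23	functional
TRBV4-1	human	TRB	V	4	forward	none	none	spacer23	functional
TRBV5-1	human	TRB	V	5	forward	none	none	spacer23	functional
TRBV6-1	human	TRB	V	6	forward	none	none	spacer23	functional
TRBV7-1	human	TRB	V	7	forward	none	none	spacer23	pseudogene
TRBV4-2	human	TRB	V	8	forward	none	none	spacer23	functional
TRBV6-2	human	TRB	V	9	forward	none	none	spacer23	functional
TRBV3-2	human	TRB	V	10	forward	none	none	spacer23	pseudogene
TRBV4-3	human	TRB	V	11	forward	none	none	spacer23	functional
TRBV6-3	human	TRB	V	12	forward	none	none	spacer23	functional
TRBV7-2	human	TRB	V	13	forward	none	none	spacer23	functional
TRBV8-1	human	TRB	V	14	forward	none	none	spacer23	pseudogene
TRBV5-2	human	TRB	V	15	forward	none	none	spacer23	pseudogene
TRBV6-4	human	TRB	V	16	forward	none	none	spacer23	functional
TRBV7-3	human	TRB	V	17	forward	none	none	spacer23	functional
TRBV8-2	human	TRB	V	18	forward	none	none	spacer23	pseudogene
TRBV5-3	human	TRB	V	19	forward	none	none	spacer23	ORF
TRBV9	human	TRB	V	20	forward	none	none	spacer23	functional
TRBV10-1	human	TRB	V	21	forward	none	none	spacer23	functional
TRBV11-1	human	TRB	V	22	forward	none	none	spacer23	functional
TRBV12-1	human	TRB	V	23	forward	none	none	spacer23	pseudogene
TRBV10-2	human	TRB	V	24	forward	none	none	spacer23	functional
TRBV11-2	human	TRB	V	25	forward	none	none	spacer23	functional
TRBV12-2	human	TRB	V	26	forward	none	none	spacer23	pseudogene
TRBV6-5	human	TRB	V	27	forward	none	none	spacer23	functional
TRBV7-4	human	TRB	V	28	forward	none	none	spacer23	functional
TRBV5-4	human	TRB	V	29	forward	none	none	spacer23	functional
TRBV6-6	human	TRB	V	30	forward	none	none	spacer23	functional
TRBV7-5	human	TRB	V	31	forward	none	none	spacer23	pseudogene
TRBV5-5	human	TRB	V	32	forward	none	none	spacer23	functional
TRBV6-7	human	TRB	V	33	forward	none	none	spacer23	ORF
TRBV7-6	human	TRB	V	34	forward	none	none	spacer23	functional
TRBV5-6	human	TRB	V	35	forward	none	none	spacer23	functional
TRBV6-8	human	TRB	V	36	forward	none	none	spacer23	functional
TRBV7-7	human	TRB	V	37	forward	none	none	spacer23	functional
TRBV5-7	human	TRB	V	38	forward	none	none	spacer23	ORF
TRBV6-9	human	TRB	V	39	forward	none	none	spacer23	functional
TRBV7-8	human	TRB	V	40	forward	none	none	spacer23	functional
TRBV5-8	human	TRB	V	41	forward	none	none	spacer23	functional
TRBV7-9	human	TRB	V	42	forward	none	none	spacer23	functional
TRBV13	human	TRB	V	43	forward	none	none	spacer23	functional
TRBV10-3	human	TRB	V	44	forward	none	none	spacer23	functional
TRBV11-3	human	TRB	V	45	forward	none	none	spacer23	functional
TRBV12-3	human	TRB	V	46	forward	none	none	spacer23	functional
TRBV12-4	human	TRB	V	47	forward	none	none	spacer23	functional
TRBV12-5	human	TRB	V	48	forward	none	none	spacer23	functional
TRBV14	human	TRB	V	49	forward	none	none	spacer23	functional
TRBV15	human	TRB	V	50	forward	none	none	spacer23	functional
TRBV16	human	TRB	V	51	forward	none	none	spacer23	functional
TRBV17	human	TRB	V	52	forward	none	none	spacer23	ORF
TRBV18	human	TRB	V	53	forward	none	none	spacer23	functional
TRBV19	human	TRB	V	54	forward	none	none	spacer23	functional
TRBV20-1	human	TRB	V	55	forward	none	none	spacer23	functional
TRBV21-1	human	TRB	V	56	forward	none	none	spacer23	pseudogene
TRBV22-1	human	TRB	V	57	forward	none	none	spacer23	pseudogene
TRBV23-1	human	TRB	V	58	forward	none	none	spacer23	ORF
TRBV24-1	human	TRB	V	59	forward	none	none	spacer23	functional
TRBV25-1	human	TRB	V	60	forward	none	none	spacer23	functional
TRBV26	human	TRB	V	61	forward	none	none	spacer23	pseudogene
TRBV27	human	TRB	V	62	forward	none	none	spacer23	functional
TRBV28	human	TRB	V	63	forward	none	none	spacer23	functional
TRBV29-1	human	TRB	V	64	forward	none	none	spacer23	functional
TRBD1	human	TRB	D	65	forward	DJC1	spacer12	spacer23	functional
TRBJ1-1	human	TRB	J	66	forward	DJC1	spacer12	none	functional
TRBJ1-2	human	TRB	J	67	forward	DJC1	spacer12	none	functional
TRBJ1-3	human	TRB	J	68	forward	DJC1	spacer12	none	functional
TRBJ1-4	human	TRB	J	69	forward	DJC1	spacer12	none	functional
TRBJ1-5	human	TRB	J	70	forward	DJC1	spacer12	none	functional
TRBJ1-6	human	TRB	J	71	forward	DJC1	spacer12	none	functional
TRBC1	human	TRB	C	72	forward	DJC1	none	none	functional
TRBD2	human	TRB	D	73	forward	DJC2	spacer12	spacer23	functional
TRBJ2-1	human	TRB	J	74	forward	DJC2	spacer12	none	functional
TRBJ2-2	human	TRB	J	75	forward	DJC2	spacer12	none	functional
TRBJ2-3	human	TRB	J	76	forward	DJC2	spacer12	none	functional
TRBJ2-4	human	TRB	J	77	forward	DJC2	spacer12	none	functional
TRBJ2-5	human	TRB	J	78	forward	DJC2	spacer12	none	functional
TRBJ2-6	human	TRB	J	79	forward	DJC2	spacer12	none	functional
TRBJ2-7	human	TRB	J	80	forward	DJC2	spacer12	none	functional
TRBC2	human	TRB	C	81	forward	DJC2	none	none	functional
TRBV30	human	TRB	V	82	reverse	none	none	spacer23	functional
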