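name	species	locus	segment_class	ordinal	orientation	cluster	rss_5p	rss_3p	functionality
TRBV1	mouse	TRB	V	1	forward	none	none	spacer23	functional
TRBV2	mouse	TRB	V	2	forward	none	none	spacer23	functional
TRBV3	mouse	TRB	V	3	forward	none	none	spacer23	functional
TRBV4	mouse	TRB	V	4	forward	none	none	spacer23	functional
TRBV5	mouse	TRB	V	5	forward	none	none	spacer23	functional
TRBV6	mouse	TRB	V	6	forward	none	none	spacer23	pseudogene
TRBV7	mouse	TRB	V	7	forward	none	none	spacer23	pseudogene
TRBV8	mouse	TRB	V	8	forward	none	none	spacer23	pseudogene
TRBV9	mouse	TRB	V	9	forward	none	none	spacer23	pseudogene
TRBV10	mouse	TRB	V	10	forward	none	none	spacer23	ORF
TRBV11	mouse	TRB	V	11	forward	none	none	spacer23	pseudogene
TRBV12-1	mouse	TRB	V	12	forward	none	none	spacer23	functional
TRBV13-1	mouse	TRB	V	13	forward	none	none	spacer23	functional
TRBV12-2	mouse	TRB	V	14	forward	none	none	spacer23	functional
TRBV13-2	mouse	TRB	V	15	forward	none	none	spacer23	functional
TRBV12-3	mouse	TRB	V	16	forward	none	none	spacer23	ORF
TRBV13-3	mouse	TRB	V	17	forward	none	none	spacer23	functional
TRBV14	mouse	TRB	V	18	forward	none	none	spacer23	functional
TRBV15	mouse	TRB	V	19	forward	none	none	spacer23	functional
TRBV16	mouse	TRB	V	20	forward	none	none	spacer23	functional
TRBV17	mouse	TRB	V	21	forward	none	none	spacer23	functional
TRBV18	mouse	TRB	V	22	forward	none	none	spacer23	pseudogene
TRBV19	mouse	TRB	V	23	forward	none	none	spacer23	functional
TRBV20	mouse	TRB	V	24	forward	none	none	spacer23	functional
TRBV21	mouse	TRB	V	25	forward	none	none	spacer23	pseudogene
TRBV22	mouse	TRB	V	26	forward	none	none	spacer23	pseudogene
TRBV23	mouse	TRB	V	27	forward	none	none	spacer23	functional
TRBV24	mouse	TRB	V	28	forward	none	none	spacer23	functional
TRBV25	mouse	TRB	V	29	forward	none	none	spacer23	pseudogene
TRBV26	mouse	TRB	V	30	forward	none	none	spacer23	functional
TRBV29	mouse	TRB	V	31	forward	none	none	spacer23	functional
TRBD1	mouse	TRB	D	32	forward	DJC1	spacer12	spacer23	functional
TRBJ1-1	mouse	TRB	J	33	forward	DJC1	spacer12	none	functional
TRBJ1-2	mouse	TRB	J	34	forward	DJC1	spacer12	none	functional
TRBJ1-3	mouse	TRB	J	35	forward	DJC1	spacer12	none	functional
TRBJ1-4	mouse	TRB	J	36	forward	DJC1	spacer12	none	functional
TRBJ1-5	mouse	TRB	J	37	forward	DJC1	spacer12	none	functional
TRBJ1-6	mouse	TRB	J	38	forward	DJC1	spacer12	none	functional
TRBJ1-7	mouse	TRB	J	39	forward	DJC1	spacer12	none	pseudogene
TRBC1	mouse	TRB	C	40	forward	DJC1	none	none	functional
TRBD2	mouse	TRB	D	41	forward	DJC2	spacer12	spacer23	functional
TRBJ2-1	mouse	TRB	J	42	forward	DJC2	spacer12	none	functional
TRBJ2-2	mouse	TRB	J	43	forward	DJC2	spacer12	none	functional
TRBJ2-3	mouse	TRB	J	44	forward	DJC2	spacer12	none	functional
TRBJ2-4	mouse	TRB	J	45	forward	DJC2	spacer12	none	functional
TRBJ2-5	mouse	TRB	J	46	forward	DJC2	spacer12	none	functional
TRBJ2-6	mouse	TRB	J	47	forward	DJC2	spacer12	none	pseudogene
TRBJ2-7	mouse	TRB	J	48	forward	DJC2	spacer12	none	functional
TRBC2	mouse	TRB	C	49	forward	DJC2	none	none	functional
TRBV31	mouse	TRB	V	50	reverse	none	none	spacer23	functional
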