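name	species	locus	segment_class	ordinal	orientation	cluster	rss_5p	rss_3p	functionality
TOYV1	toy	TRB	V	1	forward	none	none	spacer23	functional
TOYV2	toy	TRB	V	2	forward	none	none	spacer23	functional
TOYV3	toy	TRB	V	3	forward	none	none	spacer23	functional
TOYD1	toy	TRB	D	4	forward	DJC1	spacer12	spacer23	functional
TOYJ1-1	toy	TRB	J	5	forward	DJC1	spacer12	none	functional
TOYJ1-2	toy	TRB	J	6	forward	DJC1	spacer12	none	functional
TOYC1	toy	TRB	C	7	forward	DJC1	none	none	functional
TOYD2	toy	TRB	D	8	forward	DJC2	spacer12	spacer23	functional
TOYJ2-1	toy	TRB	J	9	forward	DJC2	spacer12	none	functional
TOYJ2-2	toy	TRB	J	10	forward	DJC2	spacer12	none	functional
TOYC2	toy	TRB	C	11	forward	DJC2	none	none	functional
TOYVR	toy	TRB	V	12	reverse	none	none	spacer23	functional
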