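name	species	locus	segment_class	ordinal	orientation	cluster	rss_5p	rss_3p	functionality
TOYAV1	toy	TRA	V	1	forward	none	none	spacer23	functional
TOYAV2	toy	TRA	V	2	forward	none	none	spacer23	functional
TOYAV3	toy	TRA	V	3	forward	none	none	spacer23	functional
TOYAJ3	toy	TRA	J	4	forward	none	spacer12	none	functional
TOYAJ2	toy	TRA	J	5	forward	none	spacer12	none	functional
TOYAJ1	toy	TRA	J	6	forward	none	spacer12	none	functional
TOYAC	toy	TRA	C	7	forward	none	none	none	functional
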