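1	Agrobacterium	agrobacterium	PROPN	_	_	3	compound	_	_
2	rhizogenes	rhizogenes	PROPN	_	_	1	flat	_	_
3	strains	strains	NOUN	_	_	8	nsubj	_	_
4	of	of	ADP	_	_	7	case	_	_
5	the	the	DET	_	_	7	det	_	_
6	agropine	agropine	ADJ	_	_	7	amod	_	_
7	type	type	NOUN	_	_	3	nmod	_	_
8	harbor	harbor	VERB	_	_	0	root	_	_
9	on	on	ADP	_	_	11	case	_	_
10	their	their	PRON	_	_	11	nmod:poss	_	_
11	Ri-plasmid	ri-plasmid	PROPN	_	_	8	obl	_	_
12	two	two	NUM	_	_	13	nummod	_	_
13	T-DNAs	t-dnas	NOUN	_	_	8	obj	_	_
14	,	,	PUNCT	_	_	17	punct	_	_
15	a	a	DET	_	_	17	det	_	_
16	left	left	ADJ	_	_	17	amod	_	_
17	TL-DNA	tl-dna	NOUN	_	_	13	appos	_	_
18	and	and	CCONJ	_	_	21	cc	_	_
19	a	a	DET	_	_	21	det	_	_
20	right	right	ADJ	_	_	21	amod	_	_
21	TR-DNA	tr-dna	NOUN	_	_	17	conj	_	_
22	.	.	PUNCT	_	_	8	punct	_	_

1	The	the	DET	_	_	3	det	_	_
2	rolB	rolb	PROPN	_	_	3	compound	_	_
3	gene	gene	NOUN	_	_	10	nsubj	_	_
4	of	of	ADP	_	_	6	case	_	_
5	the	the	DET	_	_	6	det	_	_
6	TL-DNA	tl-dna	PROPN	_	_	3	nmod	_	_
7	is	is	AUX	_	_	10	cop	_	_
8	the	the	DET	_	_	10	det	_	_
9	major	major	ADJ	_	_	10	amod	_	_
10	factor	factor	NOUN	_	_	0	root	_	_
11	in	in	ADP	_	_	13	case	_	_
12	the	the	DET	_	_	13	det	_	_
13	pathogenesis	pathogenesis	NOUN	_	_	10	nmod	_	_
14	of	of	ADP	_	_	17	case	_	_
15	the	the	DET	_	_	17	det	_	_
16	hairy-root	hairy-root	ADJ	_	_	17	amod	_	_
17	disease	disease	NOUN	_	_	13	nmod	_	_
18	and	and	CCONJ	_	_	22	cc	_	_
19	its	its	PRON	_	_	21	nmod:poss	_	_
20	constitutive	constitutive	ADJ	_	_	21	amod	_	_
21	expression	expression	NOUN	_	_	22	nsubj	_	_
22	interfere	interfere	VERB	_	_	10	conj	_	_
23	profoundly	profoundly	ADV	_	_	22	advmod	_	_
24	with	with	ADP	_	_	26	case	_	_
25	plant	plant	NOUN	_	_	26	compound	_	_
26	morphogenesis	morphogenesis	NOUN	_	_	22	obl	_	_
27	.	.	PUNCT	_	_	10	punct	_	_

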