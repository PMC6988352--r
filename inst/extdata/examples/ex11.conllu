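1	We	we	PRON	_	_	2	nsubj	_	_
2	present	present	VERB	_	_	0	root	_	_
3	the	the	DET	_	_	5	det	_	_
4	real-time	real-time	ADJ	_	_	5	amod	_	_
5	monitoring	monitoring	NOUN	_	_	2	obj	_	_
6	of	of	ADP	_	_	12	case	_	_
7	hydrogen	hydrogen	NOUN	_	_	8	compound	_	_
8	cyanide	cyanide	NOUN	_	_	12	compound	_	_
9	(	(	PUNCT	_	_	10	punct	_	_
10	HCN	hcn	PROPN	_	_	8	appos	_	_
11	)	)	PUNCT	_	_	10	punct	_	_
12	production	production	NOUN	_	_	5	nmod	_	_
13	from	from	ADP	_	_	20	case	_	_
14	Pseudomonas	pseudomonas	PROPN	_	_	20	compound	_	_
15	aeruginosa	aeruginosa	PROPN	_	_	14	flat	_	_
16	(	(	PUNCT	_	_	17	punct	_	_
17	P.	p.	PROPN	_	_	14	appos	_	_
18	aeruginosa	aeruginosa	PROPN	_	_	17	flat	_	_
19	)	)	PUNCT	_	_	17	punct	_	_
20	strains	strains	NOUN	_	_	12	nmod	_	_
21	in	in	ADP	_	_	22	case	_	_
22	vitro	vitro	NOUN	_	_	20	nmod	_	_
23	,	,	PUNCT	_	_	2	punct	_	_
24	using	using	VERB	_	_	2	advcl	_	_
25	laser-based	laser-based	ADJ	_	_	27	amod	_	_
26	photoacoustic	photoacoustic	ADJ	_	_	27	amod	_	_
27	spectroscopy	spectroscopy	NOUN	_	_	24	obj	_	_
28	.	.	PUNCT	_	_	2	punct	_	_

1	Both	both	CCONJ	_	_	3	cc	_	_
2	reference	reference	NOUN	_	_	3	compound	_	_
3	strains	strains	NOUN	_	_	12	nsubj:pass	_	_
4	and	and	CCONJ	_	_	6	cc	_	_
5	clinical	clinical	ADJ	_	_	6	amod	_	_
6	isolates	isolates	NOUN	_	_	3	conj	_	_
7	of	of	ADP	_	_	8	case	_	_
8	patients	patients	NOUN	_	_	6	nmod	_	_
9	with	with	ADP	_	_	10	case	_	_
10	CF	cf	PROPN	_	_	8	nmod	_	_
11	were	were	AUX	_	_	12	aux:pass	_	_
12	studied	studied	VERB	_	_	0	root	_	_
13	,	,	PUNCT	_	_	15	punct	_	_
14	and	and	CCONJ	_	_	15	cc	_	_
15	compared	compared	VERB	_	_	12	conj	_	_
16	to	to	ADP	_	_	18	case	_	_
17	other	other	ADJ	_	_	18	amod	_	_
18	pathogens	pathogens	NOUN	_	_	15	obl	_	_
19	commonly	commonly	ADV	_	_	20	advmod	_	_
20	present	present	ADJ	_	_	18	amod	_	_
21	in	in	ADP	_	_	22	case	_	_
22	lungs/airways	lungs/airways	NOUN	_	_	20	obl	_	_
23	of	of	ADP	_	_	25	case	_	_
24	CF	cf	PROPN	_	_	25	compound	_	_
25	patients	patients	NOUN	_	_	22	nmod	_	_
26	.	.	PUNCT	_	_	12	punct	_	_

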