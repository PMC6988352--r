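1	In	in	ADP	_	_	3	case	_	_
2	previous	previous	ADJ	_	_	3	amod	_	_
3	studies	studies	NOUN	_	_	10	obl	_	_
4	of	of	ADP	_	_	5	case	_	_
5	S.	s.	PROPN	_	_	3	nmod	_	_
6	marcescens	marcescens	PROPN	_	_	5	flat	_	_
7	MG1	mg1	PROPN	_	_	5	flat	_	_
8	,	,	PUNCT	_	_	10	punct	_	_
9	we	we	PRON	_	_	10	nsubj	_	_
10	showed	showed	VERB	_	_	0	root	_	_
11	that	that	SCONJ	_	_	15	mark	_	_
12	biofilm	biofilm	NOUN	_	_	13	compound	_	_
13	maturation	maturation	NOUN	_	_	15	nsubj:pass	_	_
14	was	was	AUX	_	_	15	aux:pass	_	_
15	influenced	influenced	VERB	_	_	10	ccomp	_	_
16	by	by	ADP	_	_	18	case	_	_
17	quorum	quorum	NOUN	_	_	18	compound	_	_
18	sensing	sensing	NOUN	_	_	15	obl	_	_
19	.	.	PUNCT	_	_	10	punct	_	_

1	Because	because	ADP	_	_	4	case	_	_
2	of	of	ADP	_	_	1	fixed	_	_
3	the	the	DET	_	_	4	det	_	_
4	importance	importance	NOUN	_	_	16	obl	_	_
5	of	of	ADP	_	_	6	case	_	_
6	adhesion	adhesion	NOUN	_	_	4	nmod	_	_
7	in	in	ADP	_	_	8	mark	_	_
8	initiating	initiating	VERB	_	_	6	acl	_	_
9	biofilm	biofilm	NOUN	_	_	10	compound	_	_
10	formation	formation	NOUN	_	_	8	obj	_	_
11	and	and	CCONJ	_	_	12	cc	_	_
12	infection	infection	NOUN	_	_	10	conj	_	_
13	,	,	PUNCT	_	_	16	punct	_	_
14	the	the	DET	_	_	16	det	_	_
15	primary	primary	ADJ	_	_	16	amod	_	_
16	goal	goal	NOUN	_	_	0	root	_	_
17	of	of	ADP	_	_	19	case	_	_
18	this	this	DET	_	_	19	det	_	_
19	study	study	NOUN	_	_	16	nmod	_	_
20	was	was	AUX	_	_	16	cop	_	_
21	to	to	PART	_	_	22	mark	_	_
22	determine	determine	VERB	_	_	16	acl	_	_
23	whether	whether	SCONJ	_	_	26	mark	_	_
24	QS	qs	PROPN	_	_	26	nsubj	_	_
25	is	is	AUX	_	_	26	cop	_	_
26	important	important	ADJ	_	_	22	ccomp	_	_
27	in	in	ADP	_	_	28	case	_	_
28	adhesion	adhesion	NOUN	_	_	26	obl	_	_
29	to	to	ADP	_	_	34	case	_	_
30	both	both	CCONJ	_	_	31	cc	_	_
31	abiotic	abiotic	ADJ	_	_	34	amod	_	_
32	and	and	CCONJ	_	_	33	cc	_	_
33	biotic	biotic	ADJ	_	_	31	conj	_	_
34	surfaces	surfaces	NOUN	_	_	28	nmod	_	_
35	.	.	PUNCT	_	_	16	punct	_	_

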