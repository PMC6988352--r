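1	To	to	PART	_	_	2	mark	_	_
2	evaluate	evaluate	VERB	_	_	0	root	_	_
3	the	the	DET	_	_	5	det	_	_
4	growth	growth	NOUN	_	_	5	compound	_	_
5	potential	potential	NOUN	_	_	2	obj	_	_
6	of	of	ADP	_	_	10	case	_	_
7	F.	f.	PROPN	_	_	10	compound	_	_
8	tularensis	tularensis	PROPN	_	_	7	flat	_	_
9	LVS	lvs	PROPN	_	_	7	flat	_	_
10	strain	strain	NOUN	_	_	5	nmod	_	_
11	in	in	ADP	_	_	15	case	_	_
12	macrophage-like	macrophage-like	ADJ	_	_	15	amod	_	_
13	cell	cell	NOUN	_	_	15	compound	_	_
14	line	line	NOUN	_	_	15	compound	_	_
15	J774	j774	PROPN	_	_	10	nmod	_	_
16	modulated	modulated	VERB	_	_	15	acl	_	_
17	by	by	ADP	_	_	19	case	_	_
18	host	host	NOUN	_	_	19	compound	_	_
19	cells	cells	NOUN	_	_	16	obl	_	_
20	.	.	PUNCT	_	_	2	punct	_	_

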