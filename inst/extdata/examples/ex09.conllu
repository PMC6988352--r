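1	All	all	PRON	_	_	13	nsubj	_	_
2	but	but	ADP	_	_	3	case	_	_
3	1	1	NUM	_	_	1	nmod	_	_
4	of	of	ADP	_	_	7	case	_	_
5	the	the	DET	_	_	7	det	_	_
6	12	12	NUM	_	_	7	nummod	_	_
7	people	people	NOUN	_	_	1	nmod	_	_
8	with	with	ADP	_	_	12	case	_	_
9	V.	v.	PROPN	_	_	12	compound	_	_
10	cholerae	cholerae	PROPN	_	_	9	flat	_	_
11	O:1	o:1	PROPN	_	_	9	flat	_	_
12	infection	infection	NOUN	_	_	7	nmod	_	_
13	gave	gave	VERB	_	_	0	root	_	_
14	a	a	DET	_	_	15	det	_	_
15	history	history	NOUN	_	_	13	obj	_	_
16	of	of	ADP	_	_	18	case	_	_
17	recent	recent	ADJ	_	_	18	amod	_	_
18	consumption	consumption	NOUN	_	_	15	nmod	_	_
19	of	of	ADP	_	_	21	case	_	_
20	marine	marine	ADJ	_	_	21	amod	_	_
21	bivalves	bivalves	NOUN	_	_	18	nmod	_	_
22	known	known	VERB	_	_	21	acl	_	_
23	locally	locally	ADV	_	_	22	advmod	_	_
24	as	as	ADP	_	_	25	case	_	_
25	arselle	arselle	NOUN	_	_	22	obl	_	_
26	(	(	PUNCT	_	_	27	punct	_	_
27	pelecypods	pelecypods	NOUN	_	_	25	appos	_	_
28	)	)	PUNCT	_	_	27	punct	_	_
29	.	.	PUNCT	_	_	13	punct	_	_

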