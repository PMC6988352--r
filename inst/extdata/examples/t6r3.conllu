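1	Methicillin-resistant	methicillin-resistant	ADJ	_	_	3	amod	_	_
2	Staphylococcus	staphylococcus	PROPN	_	_	3	compound	_	_
3	aureus	aureus	PROPN	_	_	7	compound	_	_
4	(	(	PUNCT	_	_	5	punct	_	_
5	MRSA	mrsa	PROPN	_	_	3	appos	_	_
6	)	)	PUNCT	_	_	5	punct	_	_
7	colonization	colonization	NOUN	_	_	17	nsubj:pass	_	_
8	in	in	ADP	_	_	12	case	_	_
9	a	a	DET	_	_	12	det	_	_
10	skilled	skilled	ADJ	_	_	12	amod	_	_
11	nursing	nursing	NOUN	_	_	12	compound	_	_
12	facility	facility	NOUN	_	_	7	nmod	_	_
13	(	(	PUNCT	_	_	14	punct	_	_
14	SNF	snf	PROPN	_	_	12	appos	_	_
15	)	)	PUNCT	_	_	14	punct	_	_
16	was	was	AUX	_	_	17	aux:pass	_	_
17	reported	reported	VERB	_	_	0	root	_	_
18	.	.	PUNCT	_	_	17	punct	_	_

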