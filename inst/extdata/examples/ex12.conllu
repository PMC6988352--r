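1	Prospective	prospective	ADJ	_	_	4	amod	_	_
2	screening	screening	NOUN	_	_	4	compound	_	_
3	culture	culture	NOUN	_	_	4	compound	_	_
4	surveillance	surveillance	NOUN	_	_	14	nsubj:pass	_	_
5	for	for	ADP	_	_	6	case	_	_
6	MRSA	mrsa	PROPN	_	_	4	nmod	_	_
7	among	among	ADP	_	_	8	case	_	_
8	patients	patients	NOUN	_	_	4	nmod	_	_
9	in	in	ADP	_	_	12	case	_	_
10	a	a	DET	_	_	12	det	_	_
11	community	community	NOUN	_	_	12	compound	_	_
12	SNF	snf	PROPN	_	_	8	nmod	_	_
13	was	was	AUX	_	_	14	aux:pass	_	_
14	performed	performed	VERB	_	_	0	root	_	_
15	.	.	PUNCT	_	_	14	punct	_	_

1	Nares	nares	NOUN	_	_	5	compound	_	_
2	and	and	CCONJ	_	_	3	cc	_	_
3	stool	stool	NOUN	_	_	1	conj	_	_
4	swab	swab	NOUN	_	_	5	compound	_	_
5	cultures	cultures	NOUN	_	_	7	nsubj:pass	_	_
6	were	were	AUX	_	_	7	aux:pass	_	_
7	obtained	obtained	VERB	_	_	0	root	_	_
8	from	from	ADP	_	_	11	case	_	_
9	newly	newly	ADV	_	_	10	advmod	_	_
10	admitted	admitted	VERB	_	_	11	amod	_	_
11	patients	patients	NOUN	_	_	7	obl	_	_
12	.	.	PUNCT	_	_	7	punct	_	_

1	MRSA	mrsa	PROPN	_	_	3	nsubj:pass	_	_
2	were	were	AUX	_	_	3	aux:pass	_	_
3	isolated	isolated	VERB	_	_	0	root	_	_
4	by	by	ADP	_	_	7	case	_	_
5	oxacillin	oxacillin	NOUN	_	_	7	compound	_	_
6	screening	screening	NOUN	_	_	7	compound	_	_
7	agar	agar	NOUN	_	_	3	obl	_	_
8	.	.	PUNCT	_	_	3	punct	_	_

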