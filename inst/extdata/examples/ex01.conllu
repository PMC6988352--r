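1	None	none	PRON	_	_	6	nsubj	_	_
2	of	of	ADP	_	_	5	case	_	_
3	the	the	DET	_	_	5	det	_	_
4	colonized	colonized	ADJ	_	_	5	amod	_	_
5	children	children	NOUN	_	_	1	nmod	_	_
6	experienced	experienced	VERB	_	_	0	root	_	_
7	an	an	DET	_	_	11	det	_	_
8	invasive	invasive	ADJ	_	_	11	amod	_	_
9	K.	k.	PROPN	_	_	11	compound	_	_
10	kingae	kingae	PROPN	_	_	9	flat	_	_
11	infection	infection	NOUN	_	_	6	obj	_	_
12	.	.	PUNCT	_	_	6	punct	_	_

1	The	the	DET	_	_	2	det	_	_
2	prevalence	prevalence	NOUN	_	_	11	nsubj	_	_
3	of	of	ADP	_	_	5	case	_	_
4	pharyngeal	pharyngeal	ADJ	_	_	5	amod	_	_
5	carriage	carriage	NOUN	_	_	2	nmod	_	_
6	among	among	ADP	_	_	8	case	_	_
7	surgical	surgical	ADJ	_	_	8	amod	_	_
8	patients	patients	NOUN	_	_	5	nmod	_	_
9	was	was	AUX	_	_	11	cop	_	_
10	8.0	8.0	NUM	_	_	11	nummod	_	_
11	%	%	NOUN	_	_	0	root	_	_
12	.	.	PUNCT	_	_	11	punct	_	_

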