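1	No	no	DET	_	_	2	det	_	_
2	V.	v.	PROPN	_	_	6	nsubj:pass	_	_
3	salmonicida	salmonicida	PROPN	_	_	2	flat	_	_
4	could	could	AUX	_	_	6	aux	_	_
5	be	be	AUX	_	_	6	aux:pass	_	_
6	detected	detected	VERB	_	_	0	root	_	_
7	in	in	ADP	_	_	8	case	_	_
8	sediments	sediments	NOUN	_	_	6	obl	_	_
9	of	of	ADP	_	_	12	case	_	_
10	the	the	DET	_	_	12	det	_	_
11	fish	fish	NOUN	_	_	12	compound	_	_
12	farms	farms	NOUN	_	_	8	nmod	_	_
13	.	.	PUNCT	_	_	6	punct	_	_

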