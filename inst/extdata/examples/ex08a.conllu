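1	The	the	DET	_	_	2	det	_	_
2	interaction	interaction	NOUN	_	_	14	nsubj:pass	_	_
3	between	between	ADP	_	_	4	case	_	_
4	Streptococcus	streptococcus	PROPN	_	_	2	nmod	_	_
5	pyogenes	pyogenes	PROPN	_	_	4	flat	_	_
6	and	and	CCONJ	_	_	10	cc	_	_
7	the	the	DET	_	_	10	det	_	_
8	host	host	NOUN	_	_	10	compound	_	_
9	cell	cell	NOUN	_	_	10	compound	_	_
10	surface	surface	NOUN	_	_	4	conj	_	_
11	is	is	AUX	_	_	14	aux:pass	_	_
12	not	not	PART	_	_	14	advmod	_	_
13	completely	completely	ADV	_	_	14	advmod	_	_
14	understood	understood	VERB	_	_	0	root	_	_
15	.	.	PUNCT	_	_	14	punct	_	_

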