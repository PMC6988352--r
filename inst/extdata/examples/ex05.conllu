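1	Finding	finding	VERB	_	_	18	csubj	_	_
2	MRSA	mrsa	PROPN	_	_	3	compound	_	_
3	-contaminated	-contaminated	VERB	_	_	4	amod	_	_
4	surfaces	surfaces	NOUN	_	_	1	obj	_	_
5	on	on	ADP	_	_	7	case	_	_
6	a	a	DET	_	_	7	det	_	_
7	variety	variety	NOUN	_	_	4	nmod	_	_
8	of	of	ADP	_	_	10	case	_	_
9	environmental	environmental	ADJ	_	_	10	amod	_	_
10	surfaces	surfaces	NOUN	_	_	7	nmod	_	_
11	in	in	ADP	_	_	13	case	_	_
12	the	the	DET	_	_	13	det	_	_
13	absence	absence	NOUN	_	_	1	obl	_	_
14	of	of	ADP	_	_	17	case	_	_
15	an	an	DET	_	_	17	det	_	_
16	overt	overt	ADJ	_	_	17	amod	_	_
17	outbreak	outbreak	NOUN	_	_	13	nmod	_	_
18	emphasizes	emphasizes	VERB	_	_	0	root	_	_
19	that	that	SCONJ	_	_	23	mark	_	_
20	correctional	correctional	ADJ	_	_	21	amod	_	_
21	facilities	facilities	NOUN	_	_	23	nsubj	_	_
22	should	should	AUX	_	_	23	aux	_	_
23	have	have	VERB	_	_	18	ccomp	_	_
24	protocols	protocols	NOUN	_	_	23	obj	_	_
25	for	for	ADP	_	_	27	case	_	_
26	environmental	environmental	ADJ	_	_	27	amod	_	_
27	cleaning	cleaning	NOUN	_	_	24	nmod	_	_
28	as	as	ADP	_	_	30	case	_	_
29	a	a	DET	_	_	30	det	_	_
30	component	component	NOUN	_	_	23	obl	_	_
31	of	of	ADP	_	_	33	case	_	_
32	MRSA	mrsa	PROPN	_	_	33	compound	_	_
33	prevention	prevention	NOUN	_	_	30	nmod	_	_
34	.	.	PUNCT	_	_	18	punct	_	_

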