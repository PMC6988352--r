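1	Collectively	collectively	ADV	_	_	5	advmod	_	_
2	,	,	PUNCT	_	_	5	punct	_	_
3	these	these	DET	_	_	4	det	_	_
4	data	data	NOUN	_	_	5	nsubj	_	_
5	indicate	indicate	VERB	_	_	0	root	_	_
6	that	that	SCONJ	_	_	14	mark	_	_
7	both	both	CCONJ	_	_	8	cc	_	_
8	M.	m.	PROPN	_	_	14	nsubj	_	_
9	agassizii	agassizii	PROPN	_	_	8	flat	_	_
10	and	and	CCONJ	_	_	11	cc	_	_
11	M.	m.	PROPN	_	_	8	conj	_	_
12	testudineum	testudineum	PROPN	_	_	11	flat	_	_
13	are	are	AUX	_	_	14	cop	_	_
14	present	present	ADJ	_	_	5	ccomp	_	_
15	in	in	ADP	_	_	17	case	_	_
16	Georgia	georgia	PROPN	_	_	17	compound	_	_
17	populations	populations	NOUN	_	_	14	obl	_	_
18	of	of	ADP	_	_	20	case	_	_
19	gopher	gopher	NOUN	_	_	20	compound	_	_
20	tortoises	tortoises	NOUN	_	_	17	nmod	_	_
21	and	and	CCONJ	_	_	26	cc	_	_
22	that	that	SCONJ	_	_	26	mark	_	_
23	clinical	clinical	ADJ	_	_	24	amod	_	_
24	disease	disease	NOUN	_	_	26	nsubj	_	_
25	is	is	AUX	_	_	26	cop	_	_
26	apparent	apparent	ADJ	_	_	14	conj	_	_
27	in	in	ADP	_	_	28	case	_	_
28	populations	populations	NOUN	_	_	26	obl	_	_
29	where	where	ADV	_	_	33	advmod	_	_
30	both	both	DET	_	_	31	det	_	_
31	pathogens	pathogens	NOUN	_	_	33	nsubj	_	_
32	are	are	AUX	_	_	33	cop	_	_
33	present	present	ADJ	_	_	28	acl:relcl	_	_
34	.	.	PUNCT	_	_	5	punct	_	_

1	Additional	additional	ADJ	_	_	2	amod	_	_
2	research	research	NOUN	_	_	4	nsubj:pass	_	_
3	is	is	AUX	_	_	4	aux:pass	_	_
4	needed	needed	VERB	_	_	0	root	_	_
5	to	to	PART	_	_	7	mark	_	_
6	better	better	ADV	_	_	7	advmod	_	_
7	understand	understand	VERB	_	_	4	xcomp	_	_
8	the	the	DET	_	_	9	det	_	_
9	role	role	NOUN	_	_	7	obj	_	_
10	of	of	ADP	_	_	13	case	_	_
11	these	these	DET	_	_	13	det	_	_
12	two	two	NUM	_	_	13	nummod	_	_
13	pathogens	pathogens	NOUN	_	_	9	nmod	_	_
14	,	,	PUNCT	_	_	18	punct	_	_
15	and	and	CCONJ	_	_	18	cc	_	_
16	other	other	ADJ	_	_	18	amod	_	_
17	potential	potential	ADJ	_	_	18	amod	_	_
18	pathogens	pathogens	NOUN	_	_	13	conj	_	_
19	,	,	PUNCT	_	_	9	punct	_	_
20	in	in	ADP	_	_	23	case	_	_
21	the	the	DET	_	_	23	det	_	_
22	overall	overall	ADJ	_	_	23	amod	_	_
23	health	health	NOUN	_	_	9	nmod	_	_
24	of	of	ADP	_	_	26	case	_	_
25	tortoise	tortoise	NOUN	_	_	26	compound	_	_
26	populations	populations	NOUN	_	_	23	nmod	_	_
27	,	,	PUNCT	_	_	4	punct	_	_
28	especially	especially	ADV	_	_	33	advmod	_	_
29	if	if	SCONJ	_	_	33	mark	_	_
30	future	future	ADJ	_	_	32	amod	_	_
31	conservation	conservation	NOUN	_	_	32	compound	_	_
32	efforts	efforts	NOUN	_	_	33	nsubj	_	_
33	involve	involve	VERB	_	_	4	advcl	_	_
34	translocation	translocation	NOUN	_	_	33	obj	_	_
35	of	of	ADP	_	_	36	case	_	_
36	tortoises	tortoises	NOUN	_	_	34	nmod	_	_
37	.	.	PUNCT	_	_	4	punct	_	_

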