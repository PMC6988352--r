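1	Although	although	SCONJ	_	_	7	mark	_	_
2	A.	a.	PROPN	_	_	7	nsubj	_	_
3	aquaeolei	aquaeolei	PROPN	_	_	2	flat	_	_
4	is	is	AUX	_	_	7	aux:pass	_	_
5	most	most	ADV	_	_	6	advmod	_	_
6	closely	closely	ADV	_	_	7	advmod	_	_
7	related	related	VERB	_	_	25	advcl	_	_
8	to	to	ADP	_	_	11	case	_	_
9	purple	purple	ADJ	_	_	11	amod	_	_
10	sulfur	sulfur	NOUN	_	_	11	compound	_	_
11	bacteria	bacteria	NOUN	_	_	7	obl	_	_
12	(	(	PUNCT	_	_	14	punct	_	_
13	the	the	DET	_	_	14	det	_	_
14	genera	genera	NOUN	_	_	11	appos	_	_
15	Ectothiorhodospira	ectothiorhodospira	PROPN	_	_	14	appos	_	_
16	and	and	CCONJ	_	_	17	cc	_	_
17	Chromatium	chromatium	PROPN	_	_	15	conj	_	_
18	)	)	PUNCT	_	_	14	punct	_	_
19	,	,	PUNCT	_	_	25	punct	_	_
20	it	it	PRON	_	_	25	nsubj	_	_
21	is	is	AUX	_	_	25	cop	_	_
22	not	not	PART	_	_	25	advmod	_	_
23	a	a	DET	_	_	25	det	_	_
24	phototrophic	phototrophic	ADJ	_	_	25	amod	_	_
25	microorganism	microorganism	NOUN	_	_	0	root	_	_
26	,	,	PUNCT	_	_	29	punct	_	_
27	which	which	PRON	_	_	29	nsubj	_	_
28	is	is	AUX	_	_	29	cop	_	_
29	consistent	consistent	ADJ	_	_	25	acl:relcl	_	_
30	with	with	ADP	_	_	32	case	_	_
31	its	its	PRON	_	_	32	nmod:poss	_	_
32	isolation	isolation	NOUN	_	_	29	obl	_	_
33	from	from	ADP	_	_	36	case	_	_
34	a	a	DET	_	_	36	det	_	_
35	subterranean	subterranean	ADJ	_	_	36	amod	_	_
36	environment	environment	NOUN	_	_	32	nmod	_	_
37	.	.	PUNCT	_	_	25	punct	_	_

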