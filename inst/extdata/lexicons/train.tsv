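lemma	frequency	source	placeholder
isolate	8	train	FALSE
infection	5	train	FALSE
strain	5	train	FALSE
attachment	3	train	FALSE
adhesion	3	train	FALSE
bacteremia	2	train	FALSE
enrichment	2	train	FALSE
growth	2	train	FALSE
carriage	2	train	FALSE
resistance	2	train	FALSE
detection	1	train	FALSE
bacteriophage	1	train	FALSE
surveillance	1	train	FALSE
isolation	1	train	FALSE
elimination	1	train	FALSE
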