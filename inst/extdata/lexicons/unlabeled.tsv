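lemma	frequency	source	placeholder
strain	21256	unlabeled	FALSE
infection	12856	unlabeled	FALSE
isolate	9555	unlabeled	FALSE
prevalence	3300	unlabeled	FALSE
growth	2868	unlabeled	FALSE
detection	2621	unlabeled	FALSE
resistance	2479	unlabeled	FALSE
bacteria	1812	unlabeled	FALSE
pathogen	1711	unlabeled	FALSE
culture	1412	unlabeled	FALSE
response	1358	unlabeled	FALSE
survival	1275	unlabeled	FALSE
abundance	1196	unlabeled	FALSE
susceptibility	1161	unlabeled	FALSE
colonization	1015	unlabeled	FALSE
isolation	935	unlabeled	FALSE
transmission	853	unlabeled	FALSE
exposure	846	unlabeled	FALSE
disease	818	unlabeled	FALSE
adhesion	791	unlabeled	FALSE
attachment	300	unlabeled	TRUE
bacteremia	300	unlabeled	TRUE
enrichment	300	unlabeled	TRUE
carriage	300	unlabeled	TRUE
bacteriophage	300	unlabeled	TRUE
surveillance	300	unlabeled	TRUE
elimination	300	unlabeled	TRUE
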