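T1	Bacteria 44 56	M. agassizii
T2	Bacteria 61 75	M. testudineum
T3	Habitat 91 130	Georgia populations of gopher tortoises
T4	Habitat 358 378	tortoise populations
T5	Habitat 447 456	tortoises
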