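T1	Bacteria 9 21	A. aquaeolei
T2	Bacteria 49 71	purple sulfur bacteria
T3	Bacteria 84 102	Ectothiorhodospira
T4	Bacteria 107 117	Chromatium
T5	Habitat 132 158	phototrophic microorganism
T6	Habitat 206 230	subterranean environment
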