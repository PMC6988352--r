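T1	Bacteria 23 40	S. marcescens MG1
T2	Habitat 57 64	biofilm
T3	Habitat 162 169	biofilm
T4	Habitat 287 314	abiotic and biotic surfaces
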