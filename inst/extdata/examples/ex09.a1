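T1	Bacteria 32 47	V. cholerae O:1
T2	Habitat 98 113	marine bivalves
T3	Habitat 131 138	arselle
T4	Habitat 140 150	pelecypods
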