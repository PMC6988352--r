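T1	Bacteria 78 100	Pseudomonas aeruginosa
T2	Habitat 208 216	clinical
T3	Habitat 229 245	patients with CF
T4	Habitat 312 340	lungs/airways of CF patients
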