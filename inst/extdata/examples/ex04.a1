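T1	Bacteria 0 24	Agrobacterium rhizogenes
T2	Habitat 202 212	hairy-root
T3	Habitat 279 284	plant
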