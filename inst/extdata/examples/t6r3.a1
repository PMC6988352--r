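T1	Bacteria 0 43	Methicillin-resistant Staphylococcus aureus
T2	Bacteria 45 49	MRSA
T3	Habitat 69 93	skilled nursing facility
T4	Habitat 95 98	SNF
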