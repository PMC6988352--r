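T1	Bacteria 55 64	K. kingae
T2	Habitat 94 104	pharyngeal
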