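T1	Habitat 12 30	colonized children
T2	Bacteria 55 64	K. kingae
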