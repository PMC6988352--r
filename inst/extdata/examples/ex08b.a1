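T1	Bacteria 3 17	V. salmonicida
T2	Habitat 39 48	sediments
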