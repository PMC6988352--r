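T1	Bacteria 36 53	F. tularensis LVS
T2	Habitat 64 94	macrophage-like cell line J774
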