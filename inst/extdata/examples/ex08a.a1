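T1	Bacteria 24 46	Streptococcus pyogenes
T2	Habitat 55 64	host cell
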