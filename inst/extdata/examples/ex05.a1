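T1	Bacteria 8 12	MRSA
T2	Habitat 126 149	correctional facilities
T3	Bacteria 217 221	MRSA
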