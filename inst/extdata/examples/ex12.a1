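T1	Bacteria 47 51	MRSA
T2	Habitat 58 66	patients
T3	Habitat 101 130	Nares and stool swab cultures
T4	Habitat 165 173	patients
T5	Bacteria 175 179	MRSA
T6	Habitat 197 221	oxacillin screening agar
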