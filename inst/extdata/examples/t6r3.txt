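Methicillin-resistant Staphylococcus aureus (MRSA) colonization in a skilled nursing facility (SNF) was reported.
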