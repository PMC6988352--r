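Prospective screening culture surveillance for MRSA among patients in a community SNF was performed. Nares and stool swab cultures were obtained from newly admitted patients. MRSA were isolated by oxacillin screening agar.
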