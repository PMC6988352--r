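R1	Lives_In Bacteria:T2 Location:T1
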