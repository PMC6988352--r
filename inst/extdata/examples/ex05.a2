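R1	Lives_In Bacteria:T1 Location:T2
R2	Lives_In Bacteria:T3 Location:T2
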