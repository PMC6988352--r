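The interaction between Streptococcus pyogenes and the host cell surface is not completely understood.
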