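To evaluate the growth potential of F. tularensis LVS strain in macrophage-like cell line J774 modulated by host cells.
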