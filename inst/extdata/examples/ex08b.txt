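No V. salmonicida could be detected in sediments of the fish farms.
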