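In previous studies of S. marcescens MG1, we showed that biofilm maturation was influenced by quorum sensing. Because of the importance of adhesion in initiating biofilm formation and infection, the primary goal of this study was to determine whether QS is important in adhesion to both abiotic and biotic surfaces.
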