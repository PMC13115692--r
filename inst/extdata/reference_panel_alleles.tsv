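subpopulation	risk_alleles	chromosomes
Show/Sled-Show	23	246
Pet	6	42
Racing	9	222
Seppala	0	48
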