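cohort	dosage	cases	controls
GWAS	0	11	86
GWAS	1	9	3
GWAS	2	4	0
Sanger	0	13	24
Sanger	1	10	9
Sanger	2	1	0
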