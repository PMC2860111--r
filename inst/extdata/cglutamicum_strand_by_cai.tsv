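# Published counts of Corynebacterium glutamicum genes on the leading vs
# lagging replication strand, by codon adaptation index (CAI) bin, plus the
# ribosomal-protein reference set.
range	total	leading	lagging
CAI < 0.35	1958	1087	871
0.35 < CAI < 0.65	721	434	287
CAI > 0.65	61	41	20
Ribosomal	52	44	8
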