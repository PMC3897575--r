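population,locus,allele,N,frequency
popA,L1,A,24,0.1458
popA,L1,B,24,0.4583
popA,L1,C,24,0.2917
popA,L1,D,24,0.1042
popB,L1,A,31,0.2258
popB,L1,B,31,0.3871
popB,L1,C,31,0.2419
popB,L1,D,31,0.1452
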