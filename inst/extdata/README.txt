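synthetic_two_pops_freqs.csv
  A SYNTHETIC two-population, one-locus, four-allele sample frequency table
  in the package's frequency-table format (see ?read_frequency_table).  The
  frequencies are rounded from the copy counts 7/22/14/5 over 2N = 48
  (popA) and 14/24/15/9 over 2N = 62 (popB).  It exists to exercise the
  reader and the differentiation workflow in tests and examples; it is not
  derived from any real population.

palo1995_cinx1_sample_freqs.csv (NOT BUNDLED)
  To reproduce the published checkerspot butterfly (Melitaea cinxia) worked
  example, transcribe Table 1 of Palo et al. (1995) -- the CINX1 sample
  allele frequencies for the Praesto and Finstroem populations -- into this
  format (population, locus, allele, N, frequency) and place the file here.
  The table is under the original publisher's copyright and is therefore
  not distributed with this package.
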