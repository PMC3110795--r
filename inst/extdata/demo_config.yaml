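# Demo pipeline config: a small synthetic two-species dataset with one
# mixed-habitat contact locale, analysed end-to-end.
simulate:
  n_forest_locales: 3
  n_savanna_locales: 4
  n_mixed_locales: 1
  individuals_per_locale: 10
  n_loci: 8
  divergence_F: 0.3
  hybrid_fraction_mixed: 0.2
  savanna_Fclade_rate: 0.20
  missing_rate: 0.02
admixture:
  k_range: [1, 2, 3]
  replicates: 2
  sweeps: 150
  burnin: 50
  alpha: infer
seed: 1
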