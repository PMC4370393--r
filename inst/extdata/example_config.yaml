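# Example pipeline configuration: simulate a study-shaped dataset and run
# every stage at moderate settings.
simulate: true
seed: 42
outdir: dompop-run
stages:
  amova:
    n_perm: 999
  pairwise_fst:
    n_perm: 0
  ld: false
  hickory:
    variants: [full, f0]
    burn_in: 2000
    samples: 10000
    thin: 10
  structure:
    k_range: [1, 4]
    n_replicates: 3
    burn_in: 1000
    reps: 4000
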