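# Demonstration pipeline: a small synthetic germplasm panel run end to end.
seed: 11
out_dir: results/demo
simulate:
  n_varieties: 30
  n_qtn: 20
  n_chrom: 10
  environments: [E1, E2]
  effect_sd: 0.6
  env_corr: 0.5
  maf: [0.2, 0.5]
  mu: [8.0, 9.0]
  sigma2_G: 12.421
  sigma2_GE: 15.357
  sigma2_e: 23.949
  n_blocks: 3
mas:
  gv_floor: true
breeding:
  n_crosses: 50
  f2_sizes: [200, 500, 800]
  environments: [E1]
  cM_per_Mb: 1.0
selection:
  bin_width: 3
  goals:
    E1: 20
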