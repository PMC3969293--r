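# Example pipeline configuration: a full synthetic cohort run.
# All blocks are optional; omit one to skip that stage.
seed: 1
out_dir: numbersense-run
sessions:
  n_subjects: 200
  w_mean: 0.28
  w_sd: 0.13
  n_trials: 150
twins:
  a2: 0.32
  c2: 0.0
  e2: 0.68
  rg_os: 0.5
  n_pairs_by_group:
    MZm: 317
    MZf: 519
    DZm: 281
    DZf: 452
    DZos: 689
  missing_rate: 0.13
  models: [saturated, ACE, AE, E]
snps:
  n_individuals: 500
  n_snps: 2000
  h2_snp: 0.0
  n_causal: 0
  cutoff: .inf   # disable pruning at desk-scale marker counts
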