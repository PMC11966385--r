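# Bundled end-to-end demo: a down-scaled synthetic citrus-style cohort.
seed: 1
simulate: true
sim:
  n_chrom: 9
  chrom_len_bp: 30000000
  n_sites_per_chrom: 700
  fixed_diff_fraction: 0.3
  recomb_rate: 1.5
  n_pure_A: 6
  n_pure_B: 6
  n_candidates: 10
  n_distractors: 3
  clone_group_size: 3
  somatic_rate: 0.0001
  block_mean_bp: 5000000
  error_rate: 0.005
  missing_rate: 0.02
  cp_n_sites: 150
  cp_mut_rate: 0.001
paint:
  window_bp: 1000000
  min_sites: 5
  state_threshold: 0.8
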