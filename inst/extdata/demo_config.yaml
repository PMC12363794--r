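# Demo run: every stage on a small synthetic dataset with planted truth.
seed: 7
stages:
  synthio: true
  chromstate: true
  programs: true
  synergy: true
  rime: true
params:
  window: 2000
  gen_window: 1000
  n_perm: 200
  gsea_fdr: 0.25
  q_max: 0.05
sim:
  n_promoters: 1500
  n_cells: 400
  n_genes: 300
  n_clusters: 3
  program_effect: 1
  nb_dispersion: 0.5
  bliss_delta: 10
  noise_cv: 0.05
  n_bait_enriched: 20
  bait_rate_ratio: 20
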