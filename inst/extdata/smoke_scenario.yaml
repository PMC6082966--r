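# Reduced "smoke" scenario profile: one replicate, small genome and
# population, short chains. Useful as a fast end-to-end check of the
# scenario runner; replace with the defaults for the full study.
qtl_counts: [15]
n_replicates: 1
base_seed: 1
output_dir: pcgp_smoke_out
models:
  names: [ridge, brr, pcr-normal, pcr-eigen]
  niter: 1500
  burnin: 500
  thin: 2
genome:
  n_chromosomes: 2
  n_markers: 300
sim:
  hist_founder_females: 60
  hist_founder_males: 15
  hist_growth_generations: 20
  hist_size: 150
  hist_constant_generations: 60
  hist_final_males: 25
  recent_males: 10
  recent_females: 75
cv_folds: 3
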