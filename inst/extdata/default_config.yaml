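# Default pipeline configuration. Every analysis threshold appears here
# once; code refers to these fields, never to inline constants.
seed: 1
thresholds:
  window: 500000            # cis window, bp, inclusive boundary
  detection_fraction: 0.75  # min fraction of samples passing detection
  detection_p: 0.01         # detection p-value cutoff
  reference_range_min: 0.20 # min 95% reference range for variable probes
  outlier_n_pcs: 8          # leading PCs inspected for sample outliers
  outlier_z: 3.0            # per-PC z-score cutoff
  min_homozygote_count: 10  # rare-homozygote collapsing threshold
  q_threshold: 0.05         # significance cutoff on the q-value
  promoter_window: 1500     # bp around the TSS counted as promoter
simulation:
  n_samples: 355
  n_snps: 52
  probes_per_snp: 160
  noise_sd: 0.5
  n_true_effects: 10
  delta: 0.5                # planted effect, M-units per risk allele
annotation:
  tissues: [pbmc, liver]
enrichment:
  background: disjoint      # or all_tested
power:
  replication_n: 62
  n_model_terms: 6
  alpha: 0.05
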