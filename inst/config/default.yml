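# Default analysis configuration: every printed pipeline default in one
# place. Sections run in the listed order; each maps to one operation.
order: [prep, stats, networks, multiomics, survival, knowledge]
seed: 1
prep:
  filter_mode: max_missing
  filter_threshold: 0.5
  normalization: median
  imputation:
    method: minprob
    k: 5
    minprob_quantile: 0.01
    minprob_width: 0.3
    mixed_threshold: 0.5
stats:
  fold_change_min: 2
  fdr_max: 0.05
  fdr: bh
  permutations: 250
networks:
  method: pearson
  min_coefficient: 0.5
  fdr_max: 0.05
multiomics:
  method: spearman
  min_coefficient: 0.5
  fdr_max: 0.05
survival:
  split: 0.25
knowledge:
  k_per_label: 15
prioritization:
  max_jaccard: 0.2
  mode: union
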