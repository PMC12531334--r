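# Study configuration for the analysis workflow (desk-scale defaults).
# Every stage derives all randomness from master_seed.
output_dir: results
master_seed: 1

world:
  dims: [16, 16, 16]
  voxel_size_mm: 2
  n_networks: 4

maps:
  terms_per_network: 4
  term_noise_sd: 0.1
  n_receptors: 4
  receptor_smoothness_vox: 2
  transcriptome_sites_per_network: 12
  transcriptome_genes: 30

cohort:
  n_patients: 150
  lesion_size_vox: [15, 60]
  tract_subjects: 4
  tract_bundles_per_subject: 6

parcellation:
  K: 4
  min_component_vox: 8

ground_truth:
  networks: [1, 2]
  criterion: receptome
  overlap_threshold: 0.05
  disconnectome_threshold: 0.5

grid:
  rep_kinds: [lesion, disconnectome]
  TE: [0.9]
  RE: [0.1, 0.5]
  policies:
    - {kind: randomized, b: 0.0}
    - {kind: observable, b: 0.8}
  k_folds: 10
  configs:
    - representation: {type: embedding, method: pca, d: 10}
      learner: {kind: T, algorithm: extremely_randomized_trees}
    - representation: {type: embedding, method: nmf, d: 10}
      learner: {kind: T, algorithm: extremely_randomized_trees}
    - representation: {type: baseline, atlas: two}
      learner: {kind: T, algorithm: extremely_randomized_trees}
    - representation: {type: oracle}
      learner: {kind: T, algorithm: extremely_randomized_trees}
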