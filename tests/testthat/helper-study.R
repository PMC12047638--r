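# Small synthetic study shared across integration-style tests.
tiny_study <- function(n_subjects = 3, grid = c(12, 12, 12), n_items = 12,
                       n_animate = 6, feature_dim = 40, noise_sd = 0.5,
                       shared_fraction = 1, signal_scale = 1, seed = 1,
                       blocks = 3, trials_per_block = 24) {
  spec <- design_spec(n_subjects = n_subjects, n_sessions = 1,
                      blocks_per_session = blocks,
                      trials_per_block = trials_per_block,
                      n_items = n_items, n_animate = n_animate,
                      seed = seed)
  design <- generate_design(spec)
  features <- generate_item_features(n_items, feature_dim,
                                     within_animate_corr = 0.6,
                                     within_inanimate_corr = 0.3,
                                     n_animate = n_animate, seed = seed + 1)
  mask <- ellipsoid_mask(grid)
  truth <- ground_truth(mask, n_subjects = n_subjects,
                        feature_dim = feature_dim, noise_sd = noise_sd,
                        shared_fraction = shared_fraction,
                        signal_scale = signal_scale, seed = seed + 2)
  volumes <- generate_bold(design, features, truth, seed = seed + 3)
  list(spec = spec, design = design, features = features, mask = mask,
       truth = truth, volumes = volumes)
}

small_sphere <- function() sphere_spec(radius_mm = 2.5, voxel_size_mm = c(2, 2, 2))
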