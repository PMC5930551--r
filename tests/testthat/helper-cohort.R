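# Small cohort builders shared across test files.

tiny_cohort <- function(seed = 1, n_rois = 20, n_per = 4, n_sites = 2,
                        n_frames = 80, n_modules = 4, n_reorganised = 0,
                        n_hubs = 0, n_class_signal = 0, motion = FALSE, ...) {
  sp <- cohort_spec(n_rois = n_rois,
                    n_subjects_per_group_per_site = n_per,
                    n_sites = n_sites,
                    n_frames = rep(n_frames, n_sites),
                    tr_seconds = 2.5, site_scale = rep(1, n_sites),
                    seed = seed)
  tr <- make_ground_truth(sp, n_modules = n_modules,
                          n_reorganised = n_reorganised, n_hubs = n_hubs,
                          n_class_signal = n_class_signal, ...)
  simulate_cohort(sp, tr, motion = motion)
}

cohort_adjacencies <- function(cohort, density = 0.10) {
  lapply(cohort$timeseries, function(ts)
    threshold_to_density(correlation_matrix(ts), density))
}
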