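# Shared configuration for the analysis scripts: one deterministic
# synthetic three-site cohort with planted reorganisation, hub disruption
# and a classification signal. Every script rebuilds the cohort from this
# spec (bit-for-bit reproducible), so the scripts can be run independently.

library(painnet)

MASTER_SEED <- 20260920L

cohort_config <- function() {
  spec <- cohort_spec(n_rois = 140,
                      n_subjects_per_group_per_site = c(27, 27, 26),
                      n_sites = 3, seed = MASTER_SEED)
  truth <- make_ground_truth(spec, n_modules = 10, n_reorganised = 6,
                             n_hubs = 6, n_class_signal = 10)
  list(spec = spec, truth = truth)
}

build_cohort <- function(motion = TRUE) {
  cc <- cohort_config()
  simulate_cohort(cc$spec, cc$truth, motion = motion)
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}

write_tsv <- function(df, name) {
  path <- file.path(results_dir(), name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  path
}
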