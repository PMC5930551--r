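test_that("ground truth plants reorganisation exactly where stated", {
  sp <- cohort_spec(n_rois = 12, n_subjects_per_group_per_site = 2,
                    n_sites = 1, n_frames = 60, tr_seconds = 2.5, seed = 3)
  tr0 <- make_ground_truth(sp, n_modules = 3, n_reorganised = 0, n_hubs = 0,
                           n_class_signal = 0)
  expect_identical(tr0$partition_control, tr0$partition_pain)

  tr2 <- make_ground_truth(sp, n_modules = 3, n_reorganised = 2, n_hubs = 0,
                           n_class_signal = 0)
  differ <- which(tr2$partition_control != tr2$partition_pain)
  expect_length(differ, 2)
  expect_identical(differ, tr2$reorganised_nodes)
  expect_true(all(tr2$reorganised_nodes %in% seq_len(12)))
  # every moved node lands in a different existing module
  expect_true(all(tr2$partition_pain[differ] %in% seq_len(3)))

  # determinism
  tr2b <- make_ground_truth(sp, n_modules = 3, n_reorganised = 2, n_hubs = 0,
                            n_class_signal = 0)
  expect_identical(tr2, tr2b)

  expect_error(make_ground_truth(sp, n_modules = 13), "exceed")
  expect_error(make_ground_truth(sp, n_modules = 3, n_reorganised = 10,
                                 n_hubs = 5), "exceed")
})

test_that("simulated correlations converge to the planted block structure", {
  sp <- cohort_spec(n_rois = 24, n_subjects_per_group_per_site = 1,
                    n_sites = 1, n_frames = 5000, tr_seconds = 2.5,
                    site_scale = 1, within_module_corr = 0.6,
                    between_module_corr = 0, seed = 2)
  tr <- make_ground_truth(sp, n_modules = 3, n_reorganised = 0, n_hubs = 0,
                          n_class_signal = 0)
  r <- correlation_matrix(simulate_subject_timeseries(tr, sp, "control", 11))
  same <- outer(tr$partition_control, tr$partition_control, "==") &
    upper.tri(r)
  diff <- !outer(tr$partition_control, tr$partition_control, "==") &
    upper.tri(r)
  expect_lt(abs(mean(r[same]) - 0.6), 0.05)
  expect_lt(abs(mean(r[diff])), 0.05)
})

test_that("zero noise with a shared module latent drives same-module r to 1", {
  sp <- cohort_spec(n_rois = 12, n_subjects_per_group_per_site = 1,
                    n_sites = 1, n_frames = 200, tr_seconds = 2.5,
                    site_scale = 1, within_module_corr = 0.6,
                    between_module_corr = 0, noise_sd = 0,
                    bandpass = FALSE, seed = 2)
  tr <- make_ground_truth(sp, n_modules = 3, n_reorganised = 0, n_hubs = 0,
                          n_class_signal = 0)
  r <- correlation_matrix(simulate_subject_timeseries(tr, sp, "control", 5))
  same <- outer(tr$partition_control, tr$partition_control, "==") &
    upper.tri(r)
  expect_true(all(r[same] > 0.999))
})

test_that("pain-group series reflect the pain partition and hub attenuation", {
  sp <- cohort_spec(n_rois = 30, n_subjects_per_group_per_site = 1,
                    n_sites = 1, n_frames = 4000, tr_seconds = 2.5,
                    site_scale = 1, seed = 7)
  tr <- make_ground_truth(sp, n_modules = 3, n_reorganised = 3, n_hubs = 2,
                          n_class_signal = 0)
  r_pain <- correlation_matrix(simulate_subject_timeseries(tr, sp, "pain", 5))
  node <- tr$reorganised_nodes[1]
  new_mates <- setdiff(which(tr$partition_pain == tr$partition_pain[node]),
                       c(node, tr$reorganised_nodes, tr$disrupted_hubs))
  old_mates <- setdiff(which(tr$partition_control ==
                               tr$partition_control[node]),
                       c(node, tr$reorganised_nodes, tr$disrupted_hubs))
  expect_gt(mean(r_pain[node, new_mates]), 0.35)
  expect_lt(mean(r_pain[node, old_mates]), 0.2)

  # hub-to-target-module coupling attenuated relative to the control group
  r_ctrl <- correlation_matrix(
    simulate_subject_timeseries(tr, sp, "control", 5))
  hub <- tr$disrupted_hubs[1]
  targets <- tr$hub_targets[[as.character(hub)]]
  tnodes <- setdiff(which(tr$partition_control %in% targets),
                    c(tr$disrupted_hubs, tr$reorganised_nodes))
  expect_gt(mean(r_ctrl[hub, tnodes]) - mean(r_pain[hub, tnodes]), 0.1)
})

test_that("motion simulation is deterministic with controllable spikes", {
  m0 <- simulate_motion(50, spike_frames = integer(), spike_size_mm = 0,
                        seed = 1, drift_sd = 0)
  expect_true(all(framewise_displacement(m0) == 0))

  m1 <- simulate_motion(100, spike_frames = 50, spike_size_mm = 1.0,
                        seed = 2, drift_sd = 0.005)
  expect_gt(framewise_displacement(m1)[50], 0.5)

  m1b <- simulate_motion(100, spike_frames = 50, spike_size_mm = 1.0,
                         seed = 2, drift_sd = 0.005)
  expect_identical(m1, m1b)
  expect_error(simulate_motion(10, spike_frames = 1), "2..n_frames")
})

test_that("cohorts are reproducible bit-for-bit from spec and seed", {
  c1 <- tiny_cohort(seed = 9, n_per = 2, motion = TRUE)
  c2 <- tiny_cohort(seed = 9, n_per = 2, motion = TRUE)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$timeseries, c2$timeseries)
  expect_identical(c1$motion, c2$motion)
})

test_that("cohort files round-trip through the tab-delimited formats", {
  co <- tiny_cohort(seed = 4, n_rois = 6, n_per = 2, n_frames = 40,
                    motion = TRUE)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), nrow(co$manifest))
  id <- man$subject_id[1]
  ts <- read_timeseries(file.path(dir, paste0(id, "_timeseries.tsv")),
                        tr_seconds = 2.5)
  expect_equal(ts$data, co$timeseries[[id]]$data, tolerance = 1e-9,
               ignore_attr = TRUE)
  gt <- readLines(file.path(dir, "ground_truth.txt"))
  expect_true(any(grepl("^partition_control=", gt)))
})
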