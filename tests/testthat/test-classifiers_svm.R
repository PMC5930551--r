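test_that("univariate feature selection keeps what it should", {
  set.seed(1)
  n <- 40
  x <- matrix(rnorm(2 * n * 50), 2 * n, 50)
  y <- rep(c(TRUE, FALSE), each = n)
  x[y, 7] <- x[y, 7] + 3 # 3-SD shift on one feature
  sel <- select_features(x, y, alpha = 0.05)
  expect_true(7 %in% sel)

  # alpha = 1 keeps every finite-variance feature
  expect_length(select_features(x, y, alpha = 1), 50)

  # zero-variance features are excluded with a message
  x0 <- cbind(x, const = 1)
  expect_message(sel0 <- select_features(x0, y, alpha = 1), "zero-variance")
  expect_false(51 %in% sel0)
})

test_that("null feature retention is near the nominal alpha", {
  set.seed(2)
  hits <- replicate(200, {
    x <- matrix(rnorm(24 * 40), 24, 40)
    y <- rep(c(TRUE, FALSE), 12)
    length(select_features(x, y, alpha = 0.05))
  })
  rate <- mean(hits) / 40
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.075)
})

test_that("balanced subsampling equalises class counts per site", {
  set.seed(3)
  sites <- rep(c("A", "B"), c(20, 14))
  labels <- c(rep(c(TRUE, FALSE), c(12, 8)), rep(c(TRUE, FALSE), c(4, 10)))
  for (k in 1:10) {
    idx <- painnet:::balanced_subsample(seq_along(labels), labels, sites)
    for (s in c("A", "B")) {
      in_s <- idx[sites[idx] == s]
      expect_equal(sum(labels[in_s]), sum(!labels[in_s]))
    }
  }
})

test_that("depression labelling splits at BDI 3 and gender at F", {
  man <- data.frame(subject_id = 1:4, group = c("patient", "control",
                                                "patient", "control"),
                    bdi = c(0, 2, 3, 10), gender = c("F", "M", "M", "F"))
  expect_equal(painnet:::classifier_labels(man, "depression"),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(painnet:::classifier_labels(man, "pain"),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(painnet:::classifier_labels(man, "gender"),
               c(TRUE, FALSE, FALSE, TRUE))
})

svm_fixture <- function(seed = 31, n_class_signal = 10, coupling = 1.0) {
  co <- tiny_cohort(seed = seed, n_rois = 16, n_per = 6, n_sites = 2,
                    n_frames = 100, n_modules = 4,
                    n_class_signal = n_class_signal,
                    class_coupling = coupling)
  feats <- do.call(rbind, lapply(co$timeseries, function(ts)
    connectivity_features(correlation_matrix(ts))))
  list(cohort = co, features = feats)
}

test_that("a separable planted signal is classified correctly in both schemes", {
  fx <- svm_fixture()
  r2 <- svm_validate(fx$features, fx$cohort$manifest, scheme = "model2",
                     labelling = "pain", n_boot = 1, n_perm = 0, seed = 7,
                     c_grid = 10^c(-2, 0, 2))
  expect_gt(r2$measures["accuracy"], 0.9)

  r1 <- svm_validate(fx$features, fx$cohort$manifest, scheme = "model1",
                     labelling = "pain", n_boot = 2, n_perm = 0, seed = 7,
                     c_grid = 10^c(-2, 0, 2))
  expect_gt(r1$measures["accuracy"], 0.9)
  expect_true(all(r1$measures <= 1))
  expect_error(svm_validate(fx$features, fx$cohort$manifest,
                            scheme = "model1", holdout_site = "Z",
                            n_boot = 1, seed = 1), "absent")
})

test_that("reports are bit-reproducible for a fixed seed", {
  fx <- svm_fixture(seed = 35)
  a <- svm_validate(fx$features, fx$cohort$manifest, scheme = "model2",
                    n_boot = 2, n_perm = 5, seed = 11,
                    c_grid = 10^c(-1, 1))
  b <- svm_validate(fx$features, fx$cohort$manifest, scheme = "model2",
                    n_boot = 2, n_perm = 5, seed = 11,
                    c_grid = 10^c(-1, 1))
  expect_identical(a$measures, b$measures)
  expect_identical(a$p_values, b$p_values)
  expect_identical(a$decision_values, b$decision_values)
})

test_that("training artefacts ignore the held-out site's labels (no leakage)", {
  fx <- svm_fixture(seed = 37)
  man <- fx$cohort$manifest
  r <- svm_validate(fx$features, man, scheme = "model1", n_boot = 1,
                    n_perm = 0, seed = 3, c_grid = 10^c(-1, 1))
  man_flipped <- man
  test_rows <- man$site == "B"
  man_flipped$group[test_rows] <-
    ifelse(man$group[test_rows] == "patient", "control", "patient")
  r_flip <- svm_validate(fx$features, man_flipped, scheme = "model1",
                         n_boot = 1, n_perm = 0, seed = 3,
                         c_grid = 10^c(-1, 1))
  expect_identical(r$first_run$selected, r_flip$first_run$selected)
  expect_identical(r$first_run$cost, r_flip$first_run$cost)
})

test_that("decision-value correlations match the closed-form Pearson", {
  rep_fake <- structure(list(decision_values = c(1, 2, 3, 4, 5)),
                        class = "classifier_report")
  man <- data.frame(bdi = c(1, 2, 3, 4, 5))
  out <- decision_value_correlation(rep_fake, man)
  expect_equal(out$r, 1)

  dv <- c(0.2, -1.4, 2.2, 0.6, -0.3)
  bdi <- c(3, 9, 1, 4, 6)
  rep_fake$decision_values <- dv
  man2 <- data.frame(bdi = bdi)
  out2 <- decision_value_correlation(rep_fake, man2)
  num <- sum((dv - mean(dv)) * (bdi - mean(bdi)))
  den <- sqrt(sum((dv - mean(dv))^2) * sum((bdi - mean(bdi))^2))
  expect_equal(out2$r, num / den)

  man3 <- data.frame(bdi = rep(2, 5))
  expect_error(decision_value_correlation(rep_fake, man3), "constant")
})
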