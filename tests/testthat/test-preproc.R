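test_that("framewise displacement follows the sum-of-derivatives formula", {
  expect_equal(framewise_displacement(matrix(0.3, 5, 6)), rep(0, 5))
  m <- rbind(rep(0, 6), c(0.1, 0, 0, 0, 0, 0))
  expect_equal(framewise_displacement(m), c(0, 0.1))
  m2 <- rbind(rep(0, 6), c(0, 0, 0, 0.002, 0, 0))
  expect_equal(framewise_displacement(m2), c(0, 0.1)) # 50 mm x 0.002 rad
  # all six parameters contribute
  m3 <- rbind(rep(0, 6), c(0.1, -0.2, 0.3, 0.001, -0.001, 0.002))
  expect_equal(framewise_displacement(m3)[2], 0.6 + 50 * 0.004)
  m[2, 1] <- NaN
  expect_error(framewise_displacement(m), "non-finite")
})

test_that("scrubbing censors the offending window and unions overlaps", {
  expect_true(all(scrub(rep(0.2, 10))))
  fd <- rep(0.1, 10); fd[5] <- 0.6
  expect_identical(which(!scrub(fd)), 4:7)
  fd2 <- rep(0.1, 10); fd2[c(2, 4)] <- 0.6
  expect_identical(which(!scrub(fd2)), 1:6)
  # clipped at the series ends
  fd3 <- rep(0.1, 5); fd3[c(1, 5)] <- 0.9
  expect_identical(which(!scrub(fd3)), c(1L, 2L, 3L, 4L, 5L))
})

test_that("scrubbing is idempotent", {
  set.seed(11)
  for (k in 1:20) {
    fd <- runif(60, 0, 1)
    mask <- scrub(fd)
    fd_kept <- fd[mask]
    expect_true(all(scrub(fd_kept)))
  }
})

test_that("DVARS is the RMS frame-to-frame change and is homogeneous", {
  ts_const <- roi_timeseries(matrix(2, 10, 3), tr_seconds = 2)
  expect_equal(dvars(ts_const), rep(0, 10))
  ts2 <- roi_timeseries(rbind(c(0, 0), c(3, 4)), tr_seconds = 2)
  expect_equal(dvars(ts2)[2], sqrt((9 + 16) / 2))
  set.seed(1)
  x <- matrix(rnorm(40), 10, 4)
  expect_equal(dvars(roi_timeseries(3 * x, 2)),
               3 * dvars(roi_timeseries(x, 2)))
})

test_that("DVARS subject exclusion uses the 3-IQR fence", {
  expect_length(dvars_exclusion(c(a = 2, b = 2, c = 2, d = 2)), 0)
  v <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4, s5 = 100)
  expect_identical(dvars_exclusion(v), "s5") # Q3 + 3 IQR = 4 + 6 = 10
  # degenerate IQR = 0: only exact equality passes
  w <- c(a = 5, b = 5, c = 5, d = 5, e = 5.01)
  expect_identical(dvars_exclusion(w), "e")
})

test_that("band-pass keeps the 0.008-0.1 Hz band and kills DC/stopband", {
  tr <- 2.5
  t_sec <- (0:499) * tr
  dc <- roi_timeseries(matrix(5, 500, 1), tr_seconds = tr)
  expect_lt(max(abs(bandpass(dc)$data)), 1e-8)

  in_band <- sin(2 * pi * 0.05 * t_sec)
  out <- bandpass(roi_timeseries(cbind(in_band), tr_seconds = tr))$data
  mid <- 100:400 # away from filter edge transients
  expect_lt(abs(max(abs(out[mid])) - 1), 0.05)

  stop_band <- sin(2 * pi * 0.18 * t_sec)
  out2 <- bandpass(roi_timeseries(cbind(stop_band), tr_seconds = tr))$data
  expect_lt(max(abs(out2[mid])), 0.10)

  expect_error(bandpass(dc, low_hz = 0.1, high_hz = 0.05), "exceed")
  expect_error(bandpass(dc, high_hz = 0.25), "Nyquist")
})

test_that("nuisance regression leaves residuals orthogonal to regressors", {
  set.seed(3)
  x <- matrix(rnorm(200 * 4), 200, 4)
  ts <- roi_timeseries(x, tr_seconds = 2)
  reg <- cbind(rnorm(200), rnorm(200))
  res <- nuisance_regress(ts, reg)
  ip <- crossprod(cbind(1, reg), res$data)
  expect_lt(max(abs(ip)) / max(abs(x)), 1e-8)

  # series regressed on itself vanishes
  res2 <- nuisance_regress(ts, x)
  expect_lt(max(abs(res2$data)), 1e-8)

  # rank-deficient regressors are dropped with a message
  expect_message(nuisance_regress(ts, cbind(reg, reg[, 1])),
                 "rank-deficient")

  # regressors orthogonal to the data leave it unchanged up to mean removal
  y <- matrix(rep(c(1, -1), 100), 200, 2)
  orth <- cbind(rep(c(1, 1, -1, -1), 50))
  res3 <- nuisance_regress(roi_timeseries(y, 2), orth)
  expect_equal(res3$data, sweep(y, 2, colMeans(y)), ignore_attr = TRUE)
})

test_that("cohort preprocessing produces a sane QC table", {
  co <- tiny_cohort(seed = 8, n_rois = 10, n_per = 3, n_sites = 2,
                    n_frames = 120, motion = TRUE)
  pp <- preprocess_cohort(co)
  expect_named(pp$qc, c("subject_id", "mean_fd", "retained_fraction",
                        "mean_dvars", "excluded_flag"))
  expect_equal(nrow(pp$qc), nrow(co$manifest))
  # paper-like motion keeps most frames (loose sanity band)
  expect_true(all(pp$qc$retained_fraction > 0.6))
  expect_true(all(pp$qc$retained_fraction <= 1))
  # masks align with series length
  s1 <- pp$subjects[[1]]
  expect_length(s1$mask, nrow(s1$ts$data))
})
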