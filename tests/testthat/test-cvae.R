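test_that("backpropagated gradients match numerical differentiation", {
  set.seed(4)
  cfg <- cvae_config(n_rois = 6, n1 = 5, n2 = 4, n3 = 2)
  p <- painnet:::init_cvae_params(cfg)
  x <- matrix(rnorm(5 * 6), 5, 6)
  y <- c(0, 1, 1, 0, 1)
  eps <- matrix(rnorm(5 * 2), 5, 2)
  lg <- painnet:::cvae_loss_grad(p, x, y, eps)
  h <- 1e-6
  worst <- 0
  for (nm in names(p)) {
    for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      p2 <- p
      p2[[nm]][i] <- p2[[nm]][i] + h
      l1 <- painnet:::cvae_loss_grad(p2, x, y, eps)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h
      l0 <- painnet:::cvae_loss_grad(p2, x, y, eps)$loss
      num <- (l1 - l0) / (2 * h)
      g <- lg$grads[[nm]][i]
      worst <- max(worst, abs(g - num) / max(1e-6, abs(g) + abs(num)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("configuration accepts the full-scale widths and rejects bad ones", {
  cfg <- cvae_config(n_rois = 140, n1 = 100, n2 = 50, n3 = 10)
  expect_equal(c(cfg$n0, cfg$n1, cfg$n2, cfg$n3), c(140L, 100L, 50L, 10L))
  paper <- cvae_config(n_rois = 140, profile = "full")
  expect_equal(c(paper$n1, paper$n2, paper$n3), c(100L, 50L, 10L))
  # 10 patients + 10 controls from each of the two training sites, 50
  # samples each: the full-scale mini-batch of 2000
  expect_equal(paper$n_per_site_class * 2 * 2 * paper$n_samples_per_subject,
               2000)
  expect_error(cvae_config(n_rois = 10, n1 = 20, n2 = 30, n3 = 5))
  expect_error(cvae_config(n_rois = 10, n1 = 20, n2 = 10, n3 = 10))
})

cvae_fixture <- function(seed = 5, coupling = 1.0, n_class = 1) {
  co <- tiny_cohort(seed = seed, n_rois = 12, n_per = 4, n_sites = 2,
                    n_frames = 100, n_modules = 3,
                    n_class_signal = n_class, class_coupling = coupling)
  ts <- lapply(co$timeseries, function(t) t$data)
  list(cohort = co, ts = ts)
}

test_that("training is reproducible and the loss trace decreases", {
  fx <- cvae_fixture()
  cfg <- cvae_config(n_rois = 12, n1 = 12, n2 = 8, n3 = 2, n_iter = 120,
                     n_per_site_class = 2, n_samples_per_subject = 15,
                     seed = 9)
  m1 <- cvae_train(fx$ts, fx$cohort$manifest, cfg)
  m2 <- cvae_train(fx$ts, fx$cohort$manifest, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_trace, m2$loss_trace)
  # moving-average loss decreases from the first to the last quarter
  q <- length(m1$loss_trace) %/% 4
  expect_lt(mean(tail(m1$loss_trace, q)), mean(head(m1$loss_trace, q)))
})

test_that("a missing class at a site is reported by name", {
  fx <- cvae_fixture()
  man <- fx$cohort$manifest
  drop <- man$site == "B" & man$group == "patient"
  expect_error(cvae_train(fx$ts[man$subject_id[!drop]], man[!drop, ],
                          cvae_config(n_rois = 12, n1 = 8, n2 = 6, n3 = 2,
                                      n_iter = 5)),
               "class absent at site B")
})

test_that("per-ROI contributions sum to the reconstruction likelihood gap", {
  fx <- cvae_fixture()
  cfg <- cvae_config(n_rois = 12, n1 = 12, n2 = 8, n3 = 2, n_iter = 60,
                     n_per_site_class = 2, n_samples_per_subject = 15,
                     seed = 3)
  model <- cvae_train(fx$ts, fx$cohort$manifest, cfg)
  x <- fx$ts[[1]]
  w <- cvae_contribution_weights(model, x, 1)
  gap <- cvae_loglik(model, x, 1)$loglik_recon -
    cvae_loglik(model, x, 0)$loglik_recon
  expect_equal(sum(w), gap, tolerance = 1e-8)
  expect_length(w, 12)
})

test_that("likelihood gaps centre near zero for a class-independent cohort", {
  fx <- cvae_fixture(seed = 6, coupling = 0, n_class = 0)
  cfg <- cvae_config(n_rois = 12, n1 = 12, n2 = 8, n3 = 2, n_iter = 150,
                     n_per_site_class = 2, n_samples_per_subject = 15,
                     seed = 4)
  model <- cvae_train(fx$ts, fx$cohort$manifest, cfg)
  gaps <- vapply(fx$ts, function(x) {
    cvae_loglik(model, x, 1)$loglik_recon -
      cvae_loglik(model, x, 0)$loglik_recon
  }, numeric(1))
  n_frames <- nrow(fx$ts[[1]])
  # per-frame gap is small compared with the per-frame log-likelihood scale
  expect_lt(abs(mean(gaps)) / n_frames, 0.2)
})

test_that("likelihood ties break toward the control class", {
  fx <- cvae_fixture()
  cfg <- cvae_config(n_rois = 12, n1 = 12, n2 = 8, n3 = 2, n_iter = 10,
                     n_per_site_class = 2, n_samples_per_subject = 10,
                     seed = 2)
  model <- cvae_train(fx$ts, fx$cohort$manifest, cfg)
  # force identical conditional biases: both labels give the same density
  model$params$Ce[2, ] <- model$params$Ce[1, ]
  model$params$Cd[2, ] <- model$params$Cd[1, ]
  out <- cvae_classify(model, fx$ts[1:3])
  expect_true(all(out$loglik_gap == 0))
  expect_true(all(!out$predicted))
})

test_that("subjects with zero retained frames are rejected", {
  expect_error(painnet:::subject_frames(matrix(numeric(0), 0, 5)),
               "zero retained frames")
})
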