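two_k4 <- function() {
  a <- matrix(0, 8, 8)
  a[1:4, 1:4] <- 1; a[5:8, 5:8] <- 1; diag(a) <- 0
  a
}

test_that("multislice quality reduces to Newman-Girvan on one slice", {
  a <- two_k4()
  part <- matrix(rep(1:2, each = 4), ncol = 1)
  expect_equal(multislice_quality(list(a), part, gamma = 1, omega = 0), 0.5)
  expect_equal(multislice_quality(list(a), matrix(1, 8, 1), gamma = 1,
                                  omega = 0), 0)
  set.seed(3)
  for (k in 1:20) {
    n <- sample(4:10, 1)
    g <- random_connected_graph(n, 0.4)
    labels <- sample(1:3, n, replace = TRUE)
    gamma <- sample(c(0.5, 1, 1.5), 1)
    expect_equal(
      multislice_quality(list(g), matrix(labels, ncol = 1), gamma, 0),
      oracle_newman_girvan(g, labels, gamma))
  }
})

test_that("multislice quality matches the literal quadruple sum", {
  set.seed(4)
  for (k in 1:10) {
    n <- sample(4:6, 1); S <- sample(2:3, 1)
    stack <- replicate(S, random_connected_graph(n, 0.5), simplify = FALSE)
    part <- matrix(sample(1:3, n * S, replace = TRUE), n, S)
    gamma <- runif(1, 0.5, 2); omega <- runif(1, 0, 0.5)
    expect_equal(multislice_quality(stack, part, gamma, omega),
                 oracle_multislice(stack, part, gamma, omega))
  }
})

test_that("identical decoupled slices reproduce the single-slice quality", {
  a <- two_k4()
  part1 <- rep(1:2, each = 4)
  q1 <- multislice_quality(list(a), matrix(part1, ncol = 1), 1, 0)
  q2 <- multislice_quality(list(a, a), cbind(part1, part1), 1, 0)
  expect_equal(q2, q1)
})

test_that("partitions with missing labels are rejected", {
  a <- two_k4()
  part <- matrix(rep(1, 8), ncol = 1)
  part[3] <- NA
  expect_error(multislice_quality(list(a), part, 1, 0), "missing")
})

test_that("the optimiser recovers planted modules and beats trivial partitions", {
  cfg <- modularity_config(gamma = 1, omega = 0.1, n_subsample = 1,
                           n_reps = 1)
  fit <- optimise_partition(list(two_k4()), cfg, seed = 7)
  expect_equal(fit$Q, 0.5)
  expect_length(unique(fit$partition[, 1]), 2)
  expect_true(all(fit$partition[1:4, 1] == fit$partition[1, 1]))

  # planted 4-module stack, strong within / zero between
  set.seed(1)
  truth <- rep(1:4, each = 10)
  mk <- function() {
    m <- matrix(0, 40, 40)
    for (c in 1:4) {
      idx <- which(truth == c)
      blk <- matrix(rbinom(100, 1, 0.85), 10, 10)
      m[idx, idx] <- blk
    }
    m <- m * upper.tri(m); m + t(m)
  }
  stack <- replicate(5, mk(), simplify = FALSE)
  fit2 <- optimise_partition(stack, modularity_config(gamma = 1,
                                                      omega = 0.1), seed = 3)
  # perfect recovery up to relabelling on every slice
  for (s in 1:5) {
    tab <- table(fit2$partition[, s], truth)
    expect_true(all(rowSums(tab > 0) == 1), all(colSums(tab > 0) == 1))
  }

  # never below the trivial partitions
  set.seed(8)
  for (k in 1:5) {
    st <- replicate(2, random_connected_graph(12, 0.3), simplify = FALSE)
    cfgk <- modularity_config(gamma = 1.2, omega = 0.2, n_subsample = 1,
                              n_reps = 1)
    f <- optimise_partition(st, cfgk, seed = k)
    q_single <- multislice_quality(st, matrix(1, 12, 2), 1.2, 0.2)
    q_singletons <- multislice_quality(
      st, matrix(seq_len(24), 12, 2), 1.2, 0.2)
    expect_gte(f$Q, max(q_single, q_singletons) - 1e-12)
  }
})

test_that("dominant coupling forces identical labels across slices", {
  set.seed(6)
  stack <- replicate(4, random_connected_graph(15, 0.3), simplify = FALSE)
  fit <- optimise_partition(stack,
                            modularity_config(gamma = 1, omega = 100),
                            seed = 2)
  expect_true(all(apply(fit$partition, 1,
                        function(r) length(unique(r)) == 1)))
})

test_that("optimisation is deterministic given the seed", {
  set.seed(10)
  stack <- replicate(3, random_connected_graph(20, 0.25), simplify = FALSE)
  cfg <- modularity_config()
  f1 <- optimise_partition(stack, cfg, seed = 5)
  f2 <- optimise_partition(stack, cfg, seed = 5)
  expect_identical(f1, f2)
})

test_that("group agreement is exact for deterministic module structure", {
  # disconnected cliques: every optimisation finds exactly the cliques,
  # so agreement entries are exactly 1 (same clique) / 0 (different)
  a <- two_k4()
  cfg <- modularity_config(gamma = 1, omega = 0.1, n_subsample = 3,
                           n_reps = 4, seed = 2)
  agr <- group_agreement(replicate(4, a, simplify = FALSE), cfg)
  expect_equal(agr[1:4, 1:4], matrix(1, 4, 4))
  expect_equal(agr[1:4, 5:8], matrix(0, 4, 4))
  expect_equal(agr, t(agr))
  expect_true(all(agr >= 0 & agr <= 1))
  expect_equal(diag(agr), rep(1, 8))
})

test_that("agreement difference sums and identities", {
  p <- matrix(c(1, 0.5, 0.4,
                0.5, 1, 0.2,
                0.4, 0.2, 1), 3, 3)
  ad0 <- agreement_difference(p, p)
  expect_true(all(ad0$ad == 0))
  expect_true(all(ad0$summary$overall == 0))

  # toy: one +0.4 and one -0.3 off-diagonal entry in a column
  ctrl <- p
  pain <- p
  pain[1, 2] <- pain[2, 1] <- ctrl[1, 2] + 0.4
  pain[1, 3] <- pain[3, 1] <- ctrl[1, 3] - 0.3
  ad <- agreement_difference(pain, ctrl)
  s1 <- ad$summary[1, ]
  expect_equal(s1$positive_sum, 0.4, tolerance = 1e-9)
  expect_equal(s1$negative_sum, -0.3, tolerance = 1e-9)
  expect_equal(s1$overall, 0.7, tolerance = 1e-9)

  # antisymmetry under swapping the groups
  ad_swap <- agreement_difference(ctrl, pain)
  expect_equal(ad_swap$ad, -ad$ad)
  expect_equal(ad_swap$summary$positive_sum, -ad$summary$negative_sum)
  expect_equal(ad_swap$summary$negative_sum, -ad$summary$positive_sum)

  # overall = positive + |negative| >= each part, on random matrices
  set.seed(11)
  for (k in 1:10) {
    x <- matrix(runif(36), 6); x <- (x + t(x)) / 2; diag(x) <- 1
    y <- matrix(runif(36), 6); y <- (y + t(y)) / 2; diag(y) <- 1
    s <- agreement_difference(x, y)$summary
    expect_equal(s$overall, s$positive_sum + abs(s$negative_sum))
    expect_true(all(s$overall >= pmax(s$positive_sum,
                                      abs(s$negative_sum)) - 1e-12))
  }

  m1 <- p; dimnames(m1) <- list(letters[1:3], letters[1:3])
  m2 <- p; dimnames(m2) <- list(letters[4:6], letters[4:6])
  expect_error(agreement_difference(m1, m2), "labels")
})

test_that("permutation inference recovers planted reorganisation", {
  co <- tiny_cohort(seed = 21, n_rois = 24, n_per = 8, n_sites = 2,
                    n_frames = 120, n_modules = 4, n_reorganised = 2)
  adj <- cohort_adjacencies(co)
  cfg <- modularity_config(gamma = 1.5, omega = 0.1, n_subsample = 12,
                           n_reps = 4, n_perms = 30, seed = 5)
  pt <- reorg_permutation_test(adj, co$manifest, cfg)
  planted <- co$truth$reorganised_nodes
  top <- order(pt$result$overall, decreasing = TRUE)[1:4]
  expect_true(all(planted %in% top))
  # observed exceeds every permutation: the add-one minimum p
  expect_equal(pt$result$p_value[planted], rep(1 / 31, 2))

  pt2 <- reorg_permutation_test(adj, co$manifest, cfg)
  expect_identical(pt$result, pt2$result)
})
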