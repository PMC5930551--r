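#' Configuration for the multislice modular-reorganisation analysis
#'
#' @param gamma modularity resolution (default 1.5, which yields roughly
#'   10-20 modules on cohort-scale brain graphs).
#' @param omega categorical inter-slice coupling strength (default 0.1, a
#'   moderate coupling).
#' @param n_subsample subjects drawn per group per repetition (default 70;
#'   equalises the contribution of unequal groups).
#' @param n_reps subsampling repetitions averaged into each group's
#'   agreement matrix.
#' @param n_perms group-label permutations for inference.
#' @param seed master seed; every repetition and permutation derives its
#'   own stream from it.
#' @param profile \code{"desk"} (100 reps / 200 perms) or \code{"full"}
#'   (1000 / 1000); explicit \code{n_reps}/\code{n_perms} win.
#' @return an object of class \code{modularity_config}.
#' @export
modularity_config <- function(gamma = 1.5, omega = 0.1, n_subsample = 70,
                              n_reps = NULL, n_perms = NULL, seed = 1L,
                              profile = c("desk", "full")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full") c(1000L, 1000L) else c(100L, 200L)
  stopifnot(gamma > 0, omega >= 0, n_subsample >= 1)
  structure(list(
    gamma = gamma, omega = omega,
    n_subsample = as.integer(n_subsample),
    n_reps = as.integer(if (is.null(n_reps)) defaults[1] else n_reps),
    n_perms = as.integer(if (is.null(n_perms)) defaults[2] else n_perms),
    seed = as.integer(seed), profile = profile
  ), class = "modularity_config")
}

# Upper-triangle edge list of one binary adjacency matrix.
subject_edges <- function(a) {
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  cbind(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
}

# Convert a list of binary adjacency matrices (or precomputed edge lists)
# into the edge arrays the C++ optimiser consumes.
stack_edges <- function(adjacencies, n = NULL) {
  if (is.matrix(adjacencies[[1]]) && ncol(adjacencies[[1]]) == 2 &&
      !is.null(n)) {
    edges <- adjacencies
  } else {
    n <- nrow(adjacencies[[1]])
    edges <- lapply(adjacencies, function(a) {
      stopifnot(nrow(a) == n, ncol(a) == n)
      subject_edges(a)
    })
  }
  counts <- vapply(edges, nrow, integer(1))
  list(n = n, S = length(edges),
       ei = unlist(lapply(edges, function(e) e[, 1]), use.names = FALSE),
       ej = unlist(lapply(edges, function(e) e[, 2]), use.names = FALSE),
       es = rep.int(seq_along(edges), counts))
}

#' Categorical multislice modularity of a partition
#'
#' Evaluates
#' \deqn{Q = \frac{1}{2\mu} \sum_{ijsr} \Big[ \big(A_{ijs} - \gamma
#'   \frac{k_{is} k_{js}}{2 m_s}\big)\delta_{sr} + \delta_{ij}\,\omega\,
#'   (1 - \delta_{sr}) \Big] \delta(g_{is}, g_{jr})}
#' for a stack of binary slices (one per subject) under categorical
#' (all-pairs) inter-slice coupling, with
#' \eqn{2\mu = \sum_s 2 m_s + \omega n S (S-1)}. With a single slice and
#' \eqn{\omega = 0} this is Newman-Girvan modularity at resolution
#' \eqn{\gamma}.
#'
#' @param adjacencies list of binary symmetric adjacency matrices (shared
#'   ROI ordering).
#' @param partition integer matrix, ROIs x slices, of module labels.
#' @param gamma resolution parameter.
#' @param omega inter-slice coupling.
#' @return scalar Q.
#' @export
multislice_quality <- function(adjacencies, partition, gamma = 1.5,
                               omega = 0.1) {
  if (is.matrix(adjacencies)) adjacencies <- list(adjacencies)
  if (!is.matrix(partition)) partition <- matrix(partition, ncol = 1)
  n <- nrow(adjacencies[[1]])
  S <- length(adjacencies)
  stopifnot(nrow(partition) == n, ncol(partition) == S)
  if (anyNA(partition)) stop("partition labels missing for some (node, slice)")
  q_intra <- 0
  twom_total <- 0
  for (s in seq_len(S)) {
    a <- adjacencies[[s]]
    k <- rowSums(a)
    twom <- sum(k)
    twom_total <- twom_total + twom
    g <- partition[, s]
    same <- outer(g, g, "==")
    q_intra <- q_intra + sum(a[same])
    if (twom > 0) {
      ksum <- tapply(k, g, sum)
      q_intra <- q_intra - gamma * sum(ksum^2) / twom
    }
  }
  q_inter <- 0
  if (S > 1 && omega > 0) {
    for (i in seq_len(n)) {
      cnt <- table(partition[i, ])
      q_inter <- q_inter + omega * sum(cnt * (cnt - 1))
    }
  }
  twomu <- twom_total + omega * n * S * (S - 1)
  if (twomu == 0) return(0)
  (q_intra + q_inter) / twomu
}

#' Optimise the multislice partition (generalized Louvain)
#'
#' Greedy modularity maximisation over node-slices: randomized node-move
#' sweeps followed by community aggregation, repeated until no further
#' improvement, with the per-slice configuration null model and
#' categorical coupling of \code{\link{multislice_quality}}.
#'
#' @param adjacencies list of binary adjacency matrices (slices).
#' @param config a \code{\link{modularity_config}}.
#' @param seed optimiser seed (defaults to \code{config$seed}).
#' @return list with \code{partition} (ROIs x slices integer matrix of
#'   module labels) and \code{Q}.
#' @export
optimise_partition <- function(adjacencies, config = modularity_config(),
                               seed = config$seed) {
  if (is.matrix(adjacencies)) adjacencies <- list(adjacencies)
  stopifnot(length(adjacencies) >= 1)
  se <- stack_edges(adjacencies)
  memb <- .genlouvain_cpp(se$n, se$S, se$ei, se$ej, se$es,
                          config$gamma, config$omega,
                          as.double(seed %% 2147483647 + 1))
  list(partition = memb,
       Q = multislice_quality(adjacencies, memb, config$gamma, config$omega))
}

# Single-slice community detection at a given resolution (used as the
# default community map for the participation coefficient).
single_slice_partition <- function(a, gamma = 1, seed = 1L) {
  cfg <- modularity_config(gamma = gamma, omega = 0, n_subsample = 1,
                           n_reps = 1, n_perms = 0, seed = seed)
  as.integer(optimise_partition(list(a), cfg, seed = seed)$partition[, 1])
}

#' Group agreement (consensus) matrix by repeated subsampling
#'
#' For each repetition, draws \code{n_subsample} subjects from the group,
#' optimises the categorical multislice partition of their slices, and
#' records for every ROI pair the fraction of subject-slices in which the
#' two ROIs share a module label. The agreement matrix is the mean of
#' those co-labelling fractions over repetitions; entries lie in [0, 1]
#' and the diagonal is 1.
#'
#' @param group_adjacencies list of binary adjacency matrices, one per
#'   subject of the group.
#' @param config a \code{\link{modularity_config}}.
#' @param seed stream seed (defaults to \code{config$seed}).
#' @return n x n agreement matrix.
#' @export
group_agreement <- function(group_adjacencies, config = modularity_config(),
                            seed = config$seed) {
  n <- nrow(group_adjacencies[[1]])
  edges <- lapply(group_adjacencies, subject_edges)
  agreement <- group_agreement_edges(edges, n, config, seed)
  dimnames(agreement) <- dimnames(group_adjacencies[[1]])
  agreement
}

# Hot path: agreement from precomputed per-subject edge lists.
group_agreement_edges <- function(edges, n, config, seed) {
  n_sub <- length(edges)
  stopifnot(n_sub >= config$n_subsample)
  acc <- matrix(0, n, n)
  for (rep in seq_len(config$n_reps)) {
    rs <- child_seed(seed, rep)
    pick <- with_seed(rs, sample.int(n_sub, config$n_subsample))
    se <- stack_edges(edges[pick], n = n)
    memb <- .genlouvain_cpp(se$n, se$S, se$ei, se$ej, se$es,
                            config$gamma, config$omega,
                            as.double(rs %% 2147483647 + 1))
    acc <- acc + .colabel_fraction_cpp(memb)
  }
  agreement <- acc / config$n_reps
  diag(agreement) <- 1
  agreement
}

#' Agreement-difference matrix and per-ROI reorganisation sums
#'
#' \code{AD = pain - control} (entries in [-1, 1]). Excluding the
#' diagonal, each ROI's positive reorganisation is the sum of its positive
#' AD entries (module partners gained in pain), its negative
#' reorganisation the sum of negative entries (partners lost), and the
#' overall metric is \code{positive_sum + |negative_sum|}.
#'
#' @param pain,control group agreement matrices with identical ROI
#'   ordering.
#' @return list with \code{ad} (matrix) and \code{summary} (data frame:
#'   roi, positive_sum, negative_sum, overall).
#' @export
agreement_difference <- function(pain, control) {
  stopifnot(all(dim(pain) == dim(control)))
  if (!is.null(dimnames(pain)) && !is.null(dimnames(control)) &&
      !identical(dimnames(pain), dimnames(control))) {
    stop("ROI labels of the two agreement matrices do not match")
  }
  ad <- pain - control
  off <- ad
  diag(off) <- 0
  pos <- colSums(pmax(off, 0))
  neg <- colSums(pmin(off, 0))
  labs <- if (!is.null(colnames(ad))) colnames(ad) else
    paste0("ROI", seq_len(ncol(ad)))
  list(ad = ad,
       summary = data.frame(roi = labs,
                            positive_sum = unname(pos),
                            negative_sum = unname(neg),
                            overall = unname(pos - neg),
                            stringsAsFactors = FALSE))
}

# One full agreement-difference analysis for a given group labelling,
# on precomputed per-subject edge lists.
reorg_observed_edges <- function(edges, n, is_pain, config, seed) {
  agr_pain <- group_agreement_edges(edges[is_pain], n, config,
                                    child_seed(seed, 1))
  agr_control <- group_agreement_edges(edges[!is_pain], n, config,
                                       child_seed(seed, 2))
  agreement_difference(agr_pain, agr_control)
}

# One full agreement-difference analysis for a given group labelling.
reorg_observed <- function(adjacencies, is_pain, config, seed) {
  reorg_observed_edges(lapply(adjacencies, subject_edges),
                       nrow(adjacencies[[1]]), is_pain, config, seed)
}

#' Permutation test of per-ROI modular reorganisation
#'
#' Runs the full subsampled agreement-difference analysis on the observed
#' patient/control labelling, then \code{n_perms} times on labellings
#' obtained by randomly resampling the pooled subjects into two groups of
#' the original sizes. One-sided add-one p-values,
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (n_{perms} + 1)}, are reported per
#' ROI for the overall metric and separately for the positive sum and the
#' magnitude of the negative sum.
#'
#' @param adjacencies named/ordered list of all subjects' binary
#'   adjacency matrices.
#' @param manifest data frame with \code{subject_id} and \code{group}
#'   aligned with \code{adjacencies}.
#' @param config a \code{\link{modularity_config}}.
#' @return list with \code{ad}, \code{result} (data frame: roi,
#'   positive_sum, negative_sum, overall, p_value, p_positive,
#'   p_negative), and \code{perm_overall} (perms x ROIs matrix).
#' @export
reorg_permutation_test <- function(adjacencies, manifest,
                                   config = modularity_config()) {
  stopifnot(length(adjacencies) == nrow(manifest))
  is_pain <- manifest$group == "patient"
  stopifnot(sum(is_pain) >= config$n_subsample,
            sum(!is_pain) >= config$n_subsample)
  n_rois <- nrow(adjacencies[[1]])
  edges <- lapply(adjacencies, subject_edges)
  obs <- reorg_observed_edges(edges, n_rois, is_pain, config, config$seed)
  if (!is.null(dimnames(adjacencies[[1]]))) {
    dimnames(obs$ad) <- dimnames(adjacencies[[1]])
    obs$summary$roi <- colnames(obs$ad)
  }
  n <- nrow(obs$ad)
  ge_overall <- ge_pos <- ge_neg <- rep(0L, n)
  perm_overall <- matrix(NA_real_, config$n_perms, n)
  n_total <- length(adjacencies)
  n_pain <- sum(is_pain)
  for (p in seq_len(config$n_perms)) {
    ps <- child_seed(config$seed, 10000 + p)
    perm_pain <- rep(FALSE, n_total)
    perm_pain[with_seed(ps, sample.int(n_total, n_pain))] <- TRUE
    pr <- reorg_observed_edges(edges, n_rois, perm_pain, config, ps)
    ge_overall <- ge_overall + (pr$summary$overall >= obs$summary$overall)
    ge_pos <- ge_pos + (pr$summary$positive_sum >= obs$summary$positive_sum)
    ge_neg <- ge_neg +
      (abs(pr$summary$negative_sum) >= abs(obs$summary$negative_sum))
    perm_overall[p, ] <- pr$summary$overall
  }
  res <- obs$summary
  res$p_value <- (1 + ge_overall) / (config$n_perms + 1)
  res$p_positive <- (1 + ge_pos) / (config$n_perms + 1)
  res$p_negative <- (1 + ge_neg) / (config$n_perms + 1)
  list(ad = obs$ad, result = res, perm_overall = perm_overall)
}
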