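#' Univariate t-test feature selection
#'
#' Per-feature two-sample t-test between the classes on the training data;
#' features significant at \code{alpha} (uncorrected) are retained.
#' Zero-variance features have no defined p-value and are excluded.
#'
#' @param train_features subjects x features numeric matrix (Fisher-z
#'   connectivity values).
#' @param train_labels logical or 0/1 vector (positive class = TRUE).
#' @param alpha retention threshold (default 0.05).
#' @return integer vector of retained feature indices.
#' @export
select_features <- function(train_features, train_labels, alpha = 0.05) {
  y <- as.logical(train_labels)
  stopifnot(sum(y) >= 2, sum(!y) >= 2)
  x1 <- train_features[y, , drop = FALSE]
  x0 <- train_features[!y, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- apply(x1, 2, var); v0 <- apply(x0, 2, var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  tstat <- (m1 - m0) / se
  p <- 2 * pt(-abs(tstat), df = n1 + n0 - 2)
  keep <- which(is.finite(p) & p < alpha)
  if (any(!is.finite(p))) {
    message("select_features: excluded ", sum(!is.finite(p)),
            " zero-variance feature(s)")
  }
  keep
}

# Map a manifest to a logical label vector for the requested labelling.
classifier_labels <- function(manifest, labelling) {
  switch(labelling,
         pain = manifest$group == "patient",
         gender = manifest$gender == "F",
         depression = manifest$bdi >= 3,
         stop("unknown labelling: ", labelling))
}

# Balanced subsample: per site, keep min(#pos, #neg) of each class.
balanced_subsample <- function(idx, labels, sites) {
  keep <- integer()
  for (s in unique(sites[idx])) {
    pos <- idx[sites[idx] == s & labels[idx]]
    neg <- idx[sites[idx] == s & !labels[idx]]
    k <- min(length(pos), length(neg))
    if (k > 0) {
      keep <- c(keep, sample(pos, k), sample(neg, k))
    }
  }
  sort(keep)
}

# Standardise columns by training statistics.
standardise_train <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv, x = sweep(sweep(x, 2, mu), 2, sdv, "/"))
}
standardise_apply <- function(x, st) {
  sweep(sweep(x, 2, st$mu), 2, st$sd, "/")
}

# Fit a linear SVM and return a prediction closure.
fit_linear_svm <- function(x, y, cost) {
  fac <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  fit <- e1071::svm(x, fac, kernel = "linear", cost = cost, scale = FALSE)
  sign_flip <- if (fit$labels[1] == 2) 1 else -1 # decision value for "pos"
  list(fit = fit, predict = function(newx) {
    pr <- predict(fit, newx, decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    # e1071's decision value is positive for the first factor level seen in
    # the data; normalise so positive value = positive class
    first_pos <- levels(fac)[fit$labels[1]] == "pos"
    list(label = pr == "pos", decision = if (first_pos) dv else -dv)
  })
}

# Grid-search C by Leave-3-Out CV (random folds of 3) on the training set.
tune_cost <- function(x, y, c_grid, fold_size = 3) {
  n <- nrow(x)
  folds <- split(sample.int(n), ceiling(seq_len(n) / fold_size))
  acc <- vapply(c_grid, function(cost) {
    correct <- 0
    for (f in folds) {
      if (length(unique(y[-f])) < 2) next
      mod <- fit_linear_svm(x[-f, , drop = FALSE], y[-f], cost)
      correct <- correct + sum(mod$predict(x[f, , drop = FALSE])$label == y[f])
    }
    correct / n
  }, numeric(1))
  c_grid[which.max(acc)]
}

# One run of validation model 1 (train on all sites but the hold-out,
# test on the hold-out site) for fixed subject subsets.
run_model1 <- function(features, labels, train_idx, test_idx, alpha, c_grid) {
  sel <- select_features(features[train_idx, , drop = FALSE],
                         labels[train_idx], alpha)
  if (length(sel) == 0) sel <- seq_len(ncol(features))
  st <- standardise_train(features[train_idx, sel, drop = FALSE])
  xtr <- st$x
  xte <- standardise_apply(features[test_idx, sel, drop = FALSE], st)
  cost <- tune_cost(xtr, labels[train_idx], c_grid)
  mod <- fit_linear_svm(xtr, labels[train_idx], cost)
  pred <- mod$predict(xte)
  list(pred = pred$label, truth = labels[test_idx],
       decision = pred$decision, test_idx = test_idx,
       selected = sel, cost = cost)
}

# One run of validation model 2 (stratified leave-two-subjects-out over the
# pooled sites: each fold holds out one patient + one control of one site).
run_model2 <- function(features, labels, sites, idx, alpha, c_grid) {
  pred <- logical(0); truth <- logical(0); dec <- numeric(0)
  tidx <- integer(0)
  folds <- list()
  for (s in unique(sites[idx])) {
    pos <- sample(idx[sites[idx] == s & labels[idx]])
    neg <- sample(idx[sites[idx] == s & !labels[idx]])
    for (k in seq_len(min(length(pos), length(neg)))) {
      folds[[length(folds) + 1]] <- c(pos[k], neg[k])
    }
  }
  for (f in folds) {
    tr <- setdiff(idx, f)
    sel <- select_features(features[tr, , drop = FALSE], labels[tr], alpha)
    if (length(sel) == 0) sel <- seq_len(ncol(features))
    st <- standardise_train(features[tr, sel, drop = FALSE])
    cost <- tune_cost(st$x, labels[tr], c_grid)
    mod <- fit_linear_svm(st$x, labels[tr], cost)
    pr <- mod$predict(standardise_apply(features[f, sel, drop = FALSE], st))
    pred <- c(pred, pr$label); truth <- c(truth, labels[f])
    dec <- c(dec, pr$decision); tidx <- c(tidx, f)
  }
  list(pred = pred, truth = truth, decision = dec, test_idx = tidx)
}

svm_measures <- function(pred, truth) {
  c(accuracy = mean(pred == truth),
    sensitivity = if (any(truth)) mean(pred[truth]) else NA_real_,
    specificity = if (any(!truth)) mean(!pred[!truth]) else NA_real_)
}

# Whole validation procedure (bootstrap-averaged) for one labelling.
svm_run_all <- function(features, labels, sites, scheme, holdout_site,
                        n_boot, alpha, c_grid) {
  n <- length(labels)
  meas <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("accuracy", "sensitivity",
                                         "specificity")))
  dec_sum <- rep(0, n); dec_cnt <- rep(0L, n)
  first <- NULL
  for (b in seq_len(n_boot)) {
    if (scheme == "model1") {
      train_pool <- which(sites != holdout_site)
      test_pool <- which(sites == holdout_site)
      train_idx <- balanced_subsample(train_pool, labels, sites)
      test_idx <- balanced_subsample(test_pool, labels, sites)
      run <- run_model1(features, labels, train_idx, test_idx, alpha, c_grid)
    } else {
      idx <- balanced_subsample(seq_len(n), labels, sites)
      run <- run_model2(features, labels, sites, idx, alpha, c_grid)
    }
    if (b == 1) first <- run
    meas[b, ] <- svm_measures(run$pred, run$truth)
    dec_sum[run$test_idx] <- dec_sum[run$test_idx] + run$decision
    dec_cnt[run$test_idx] <- dec_cnt[run$test_idx] + 1L
  }
  dec <- ifelse(dec_cnt > 0, dec_sum / dec_cnt, NA_real_)
  list(measures = colMeans(meas, na.rm = TRUE), decision_values = dec,
       first_run = first)
}

#' Linear-SVM patient/control validation
#'
#' Runs the full classification procedure: per bootstrap, a balanced
#' (equal class counts per site) subsample is drawn and the entire
#' pipeline - univariate feature selection at \code{alpha}, per-feature
#' standardisation, C grid search (powers of ten, \eqn{10^{-3}} to
#' \eqn{10^3}) by Leave-3-Out CV on the training data, linear-SVM fit -
#' is executed. \code{scheme = "model1"} trains on all sites except
#' \code{holdout_site} and validates there; \code{scheme = "model2"} pools
#' all sites and uses stratified leave-two-subjects-out CV (one patient +
#' one control of the same site per fold, the C search nested inside).
#' Accuracy, sensitivity and specificity are averaged over bootstraps.
#' Permutation p-values rerun the whole procedure (bootstraps included)
#' with shuffled labels: \eqn{p = (1 + \#\{perm \ge obs\})/(n_{perm}+1)}.
#'
#' @param features subjects x features matrix (rows aligned with
#'   \code{manifest}); typically \code{\link{connectivity_features}}.
#' @param manifest data frame with \code{subject_id}, \code{site},
#'   \code{group}, \code{bdi}, \code{gender}.
#' @param scheme \code{"model1"} or \code{"model2"}.
#' @param labelling \code{"pain"}, \code{"gender"} or \code{"depression"}
#'   (BDI >= 3 vs < 3).
#' @param n_boot bootstrap repetitions.
#' @param n_perm label permutations (0 = no p-values).
#' @param seed master seed.
#' @param alpha feature-selection threshold.
#' @param c_grid SVM cost grid.
#' @param holdout_site held-out validation site for model 1.
#' @return a \code{classifier_report}: \code{measures} (accuracy,
#'   sensitivity, specificity), \code{p_values}, \code{decision_values}
#'   (per subject, NA if never in a test set), \code{first_run}
#'   (selected features, tuned cost of the first bootstrap), and the call
#'   parameters.
#' @export
svm_validate <- function(features, manifest,
                         scheme = c("model2", "model1"),
                         labelling = c("pain", "gender", "depression"),
                         n_boot = 10, n_perm = 0, seed = 1L,
                         alpha = 0.05, c_grid = 10^(-3:3),
                         holdout_site = NULL) {
  scheme <- match.arg(scheme)
  labelling <- match.arg(labelling)
  stopifnot(nrow(features) == nrow(manifest))
  labels <- classifier_labels(manifest, labelling)
  sites <- manifest$site
  if (scheme == "model1") {
    if (is.null(holdout_site)) holdout_site <- sort(unique(sites))[length(unique(sites))]
    if (!holdout_site %in% sites) stop("hold-out site absent from manifest: ",
                                       holdout_site)
  }
  obs <- with_seed(seed, svm_run_all(features, labels, sites, scheme,
                                     holdout_site, n_boot, alpha, c_grid))
  p_values <- c(accuracy = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_)
  if (n_perm > 0) {
    ge <- c(0, 0, 0)
    for (p in seq_len(n_perm)) {
      ps <- child_seed(seed, 20000 + p)
      perm_labels <- with_seed(ps, sample(labels))
      pm <- with_seed(child_seed(ps, 1),
                      svm_run_all(features, perm_labels, sites, scheme,
                                  holdout_site, n_boot, alpha, c_grid))
      ge <- ge + (pm$measures >= obs$measures)
    }
    p_values <- (1 + ge) / (n_perm + 1)
    names(p_values) <- names(obs$measures)
  }
  structure(list(measures = obs$measures, p_values = p_values,
                 decision_values = obs$decision_values,
                 first_run = obs$first_run,
                 scheme = scheme, labelling = labelling,
                 n_boot = n_boot, n_perm = n_perm, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s / %s\n", x$scheme, x$labelling))
  m <- rbind(value = x$measures, p = x$p_values[names(x$measures)])
  print(round(m, 3))
  invisible(x)
}

#' Correlation of classifier decision values with a covariate
#'
#' Pearson correlation (with two-sided p-value) between each validation
#' subject's signed distance from the decision boundary and a clinical
#' covariate such as the BDI score.
#'
#' @param report a \code{\link{svm_validate}} result.
#' @param manifest the manifest the report was computed on.
#' @param covariate manifest column name (default \code{"bdi"}).
#' @return list with \code{r}, \code{p_value}, \code{n}.
#' @export
decision_value_correlation <- function(report, manifest, covariate = "bdi") {
  dv <- report$decision_values
  ok <- !is.na(dv)
  if (sum(ok) < 3) stop("too few decision values")
  cv <- manifest[[covariate]][ok]
  if (sd(cv) == 0) stop("covariate is constant")
  ct <- cor.test(dv[ok], cv)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
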