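#' Configuration of the conditional-VAE likelihood classifier
#'
#' Architecture and training settings for the class-conditional density
#' model over per-frame ROI vectors. Encoder widths are
#' \code{(n0, n1, n2)} with latent dimension \code{n3}; the decoder
#' mirrors them. Hidden layers use layer normalisation followed by ReLU;
#' output layers are linear. The class condition enters as an extra bias
#' on the encoder's second hidden layer and the decoder's first hidden
#' layer. Training uses Adam.
#'
#' The \code{"full"} profile carries the full-scale settings
#' (widths (140, 100, 50, 10), mini-batch of 10 patients + 10 controls per
#' site x 50 samples, ensemble of 100); the default \code{"desk"} profile
#' halves the widths and shrinks batch, iterations and ensemble so the
#' model trains in seconds on one CPU.
#'
#' @param n_rois input dimension n0 (number of ROIs).
#' @param n1,n2 hidden widths; \code{n3} latent dimension
#'   (\code{n3 < n2 <= n1}).
#' @param n_iter Adam iterations (mini-batches).
#' @param n_per_site_class subjects per class drawn from each site per
#'   mini-batch.
#' @param n_samples_per_subject frames drawn per chosen subject.
#' @param alpha,beta1,beta2 Adam parameters.
#' @param n_ensemble models in the likelihood ensemble.
#' @param seed master seed.
#' @param profile \code{"desk"} or \code{"full"}; explicit arguments win.
#' @return an object of class \code{cvae_config}.
#' @export
cvae_config <- function(n_rois, n1 = NULL, n2 = NULL, n3 = NULL,
                        n_iter = NULL, n_per_site_class = NULL,
                        n_samples_per_subject = NULL,
                        alpha = 1e-3, beta1 = 0.9, beta2 = 0.999,
                        n_ensemble = NULL, seed = 1L,
                        profile = c("desk", "full")) {
  profile <- match.arg(profile)
  def <- if (profile == "full") {
    list(n1 = 100L, n2 = 50L, n3 = 10L, n_iter = 2000L,
         n_per_site_class = 10L, n_samples_per_subject = 50L,
         n_ensemble = 100L)
  } else {
    list(n1 = 50L, n2 = 25L, n3 = 5L, n_iter = 300L,
         n_per_site_class = 2L, n_samples_per_subject = 25L,
         n_ensemble = 5L)
  }
  cfg <- list(n0 = as.integer(n_rois),
              n1 = as.integer(if (is.null(n1)) def$n1 else n1),
              n2 = as.integer(if (is.null(n2)) def$n2 else n2),
              n3 = as.integer(if (is.null(n3)) def$n3 else n3),
              n_iter = as.integer(if (is.null(n_iter)) def$n_iter else n_iter),
              n_per_site_class = as.integer(
                if (is.null(n_per_site_class)) def$n_per_site_class
                else n_per_site_class),
              n_samples_per_subject = as.integer(
                if (is.null(n_samples_per_subject)) def$n_samples_per_subject
                else n_samples_per_subject),
              alpha = alpha, beta1 = beta1, beta2 = beta2,
              n_ensemble = as.integer(
                if (is.null(n_ensemble)) def$n_ensemble else n_ensemble),
              seed = as.integer(seed), profile = profile)
  stopifnot(cfg$n3 < cfg$n2, cfg$n2 <= cfg$n1)
  structure(cfg, class = "cvae_config")
}

# ---- numerics -------------------------------------------------------------

ln_eps <- 1e-5
lv_clip <- 8

# Row-wise layer normalisation; returns normalised matrix plus the cache
# needed for the backward pass.
ln_forward <- function(a) {
  m <- rowMeans(a)
  ac <- a - m
  v <- rowMeans(ac^2)
  sdv <- sqrt(v + ln_eps)
  list(y = ac / sdv, sd = sdv)
}
ln_backward <- function(dy, cache) {
  y <- cache$y
  (dy - rowMeans(dy) - y * rowMeans(dy * y)) / cache$sd
}

init_cvae_params <- function(cfg) {
  g <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)),
                                  nin, nout)
  list(W1 = g(cfg$n0, cfg$n1), b1 = numeric(cfg$n1),
       W2 = g(cfg$n1, cfg$n2), b2 = numeric(cfg$n2),
       Ce = matrix(0, 2, cfg$n2),
       Wm = g(cfg$n2, cfg$n3), bm = numeric(cfg$n3),
       Wv = g(cfg$n2, cfg$n3), bv = numeric(cfg$n3),
       W4 = g(cfg$n3, cfg$n2), b4 = numeric(cfg$n2),
       Cd = matrix(0, 2, cfg$n2),
       W5 = g(cfg$n2, cfg$n1), b5 = numeric(cfg$n1),
       W6 = g(cfg$n1, cfg$n0), b6 = numeric(cfg$n0),
       W7 = g(cfg$n1, cfg$n0), b7 = numeric(cfg$n0))
}

# Forward pass. x: B x n0; y: integer vector of 0/1; eps_z: B x n3 noise
# (NULL = deterministic z at the posterior mean, used for evaluation).
cvae_forward <- function(p, x, y, eps_z = NULL) {
  B <- nrow(x)
  Y <- cbind(1 - y, y) # one-hot, B x 2
  a1 <- sweep(x %*% p$W1, 2, p$b1, "+")
  l1 <- ln_forward(a1); h1 <- pmax(l1$y, 0)
  a2 <- sweep(h1 %*% p$W2, 2, p$b2, "+") + Y %*% p$Ce
  l2 <- ln_forward(a2); h2 <- pmax(l2$y, 0)
  mu <- sweep(h2 %*% p$Wm, 2, p$bm, "+")
  lv <- pmin(pmax(sweep(h2 %*% p$Wv, 2, p$bv, "+"), -lv_clip), lv_clip)
  z <- if (is.null(eps_z)) mu else mu + exp(0.5 * lv) * eps_z
  a3 <- sweep(z %*% p$W4, 2, p$b4, "+") + Y %*% p$Cd
  l3 <- ln_forward(a3); h3 <- pmax(l3$y, 0)
  a4 <- sweep(h3 %*% p$W5, 2, p$b5, "+")
  l4 <- ln_forward(a4); h4 <- pmax(l4$y, 0)
  xm <- sweep(h4 %*% p$W6, 2, p$b6, "+")
  xlv <- pmin(pmax(sweep(h4 %*% p$W7, 2, p$b7, "+"), -lv_clip), lv_clip)
  # per-sample, per-ROI negative reconstruction log-density
  recon_mat <- 0.5 * (xlv + (x - xm)^2 / exp(xlv) + log(2 * pi))
  kl <- 0.5 * rowSums(exp(lv) + mu^2 - 1 - lv)
  list(Y = Y, l1 = l1, h1 = h1, l2 = l2, h2 = h2, mu = mu, lv = lv,
       z = z, l3 = l3, h3 = h3, l4 = l4, h4 = h4, xm = xm, xlv = xlv,
       recon_mat = recon_mat, recon = rowSums(recon_mat), kl = kl)
}

# Mean ELBO loss over the batch and its parameter gradients.
cvae_loss_grad <- function(p, x, y, eps_z) {
  f <- cvae_forward(p, x, y, eps_z)
  B <- nrow(x)
  loss <- mean(f$recon + f$kl)
  s <- 1 / B
  # output heads
  dxm <- s * (f$xm - x) / exp(f$xlv)
  dxlv <- s * 0.5 * (1 - (x - f$xm)^2 / exp(f$xlv))
  dxlv[abs(f$xlv) >= lv_clip] <- 0
  dh4 <- dxm %*% t(p$W6) + dxlv %*% t(p$W7)
  gW6 <- t(f$h4) %*% dxm; gb6 <- colSums(dxm)
  gW7 <- t(f$h4) %*% dxlv; gb7 <- colSums(dxlv)
  da4 <- ln_backward(dh4 * (f$l4$y > 0), f$l4)
  dh3 <- da4 %*% t(p$W5)
  gW5 <- t(f$h3) %*% da4; gb5 <- colSums(da4)
  da3 <- ln_backward(dh3 * (f$l3$y > 0), f$l3)
  dz <- da3 %*% t(p$W4)
  gW4 <- t(f$z) %*% da3; gb4 <- colSums(da3)
  gCd <- t(f$Y) %*% da3
  # KL gradients plus the reparameterised path
  dmu <- dz + s * f$mu
  dlv <- s * 0.5 * (exp(f$lv) - 1)
  if (!is.null(eps_z)) dlv <- dlv + dz * eps_z * 0.5 * exp(0.5 * f$lv)
  dlv[abs(f$lv) >= lv_clip] <- 0
  dh2 <- dmu %*% t(p$Wm) + dlv %*% t(p$Wv)
  gWm <- t(f$h2) %*% dmu; gbm <- colSums(dmu)
  gWv <- t(f$h2) %*% dlv; gbv <- colSums(dlv)
  da2 <- ln_backward(dh2 * (f$l2$y > 0), f$l2)
  dh1 <- da2 %*% t(p$W2)
  gW2 <- t(f$h1) %*% da2; gb2 <- colSums(da2)
  gCe <- t(f$Y) %*% da2
  da1 <- ln_backward(dh1 * (f$l1$y > 0), f$l1)
  gW1 <- t(x) %*% da1; gb1 <- colSums(da1)
  list(loss = loss,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, Ce = gCe,
                    Wm = gWm, bm = gbm, Wv = gWv, bv = gbv,
                    W4 = gW4, b4 = gb4, Cd = gCd, W5 = gW5, b5 = gb5,
                    W6 = gW6, b6 = gb6, W7 = gW7, b7 = gb7))
}

adam_step <- function(p, grads, state, cfg) {
  state$t <- state$t + 1
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    p[[nm]] <- p[[nm]] - cfg$alpha * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + 1e-8)
  }
  list(p = p, state = state)
}

# ---- training and evaluation ---------------------------------------------

# Extract the frames x ROIs matrix from either a roi_timeseries or a
# plain matrix, applying an optional frame mask.
subject_frames <- function(x, mask = NULL) {
  m <- if (inherits(x, "roi_timeseries")) x$data else as.matrix(x)
  if (!is.null(mask)) m <- m[mask, , drop = FALSE]
  if (nrow(m) == 0) stop("subject has zero retained frames")
  m
}

#' Train one conditional VAE on a cohort's frame vectors
#'
#' Fits the class-conditional density model by Adam on the single-sample
#' ELBO (reconstruction + KL), whose negative is an upper bound of
#' \eqn{-\log p(x_j | y)}. Each mini-batch draws
#' \code{n_per_site_class} patients and controls from every site and
#' \code{n_samples_per_subject} frames from each chosen subject. ROI
#' channels are standardised with statistics pooled over the training
#' frames (stored in the model and reused at evaluation time).
#'
#' @param timeseries named list of \code{\link{roi_timeseries}} (or
#'   frames x ROIs matrices), one per training subject.
#' @param manifest data frame with \code{subject_id}, \code{site},
#'   \code{group} for the training subjects.
#' @param config a \code{\link{cvae_config}}.
#' @param seed training seed (defaults to \code{config$seed}).
#' @return an object of class \code{cvae_model} with the parameters, the
#'   standardisation, and the loss trace.
#' @export
cvae_train <- function(timeseries, manifest, config, seed = config$seed) {
  stopifnot(inherits(config, "cvae_config"),
            all(manifest$subject_id %in% names(timeseries)))
  for (s in unique(manifest$site)) {
    cls <- unique(manifest$group[manifest$site == s])
    if (!all(c("patient", "control") %in% cls)) {
      stop("class absent at site ", s)
    }
  }
  frames <- lapply(manifest$subject_id,
                   function(id) subject_frames(timeseries[[id]]))
  names(frames) <- manifest$subject_id
  stopifnot(all(vapply(frames, ncol, 1L) == config$n0))
  pooled <- do.call(rbind, frames)
  mu <- colMeans(pooled); sdv <- apply(pooled, 2, sd)
  sdv[sdv == 0] <- 1
  frames <- lapply(frames, function(m) sweep(sweep(m, 2, mu), 2, sdv, "/"))
  y_subj <- as.integer(manifest$group == "patient")
  names(y_subj) <- manifest$subject_id

  with_seed(seed, {
    p <- init_cvae_params(config)
    state <- list(t = 0,
                  m = lapply(p, function(w) w * 0),
                  v = lapply(p, function(w) w * 0))
    trace <- numeric(config$n_iter)
    for (it in seq_len(config$n_iter)) {
      ids <- unlist(lapply(unique(manifest$site), function(s) {
        c(sample(manifest$subject_id[manifest$site == s &
                                       manifest$group == "patient"],
                 config$n_per_site_class),
          sample(manifest$subject_id[manifest$site == s &
                                       manifest$group == "control"],
                 config$n_per_site_class))
      }))
      xb <- do.call(rbind, lapply(ids, function(id) {
        m <- frames[[id]]
        m[sample.int(nrow(m), config$n_samples_per_subject,
                     replace = nrow(m) < config$n_samples_per_subject), ,
          drop = FALSE]
      }))
      yb <- rep(y_subj[ids], each = config$n_samples_per_subject)
      eps <- matrix(rnorm(nrow(xb) * config$n3), nrow(xb), config$n3)
      lg <- cvae_loss_grad(p, xb, yb, eps)
      upd <- adam_step(p, lg$grads, state, config)
      p <- upd$p; state <- upd$state
      trace[it] <- lg$loss
    }
    structure(list(params = p, config = config, mu = mu, sd = sdv,
                   loss_trace = trace, seed = seed),
              class = "cvae_model")
  })
}

#' Log-likelihood bound of a subject's frames under a class label
#'
#' Evaluates the (negative) ELBO of every frame under condition \code{y}
#' with the latent fixed at the posterior mean, returning the subject
#' total \eqn{\log p(X|y) = \sum_j \log p(x_j|y)} (bound), its
#' reconstruction-only part, and the per-ROI reconstruction log-density
#' sums (the diagonal-Gaussian output factorises over ROIs).
#'
#' @param model a \code{\link{cvae_train}} result.
#' @param x subject frames (\code{\link{roi_timeseries}} or matrix).
#' @param y class label, 0 (control) or 1 (patient).
#' @return list with \code{loglik}, \code{loglik_recon},
#'   \code{recon_per_roi} (length n0), \code{n_frames}.
#' @export
cvae_loglik <- function(model, x, y) {
  m <- subject_frames(x)
  m <- sweep(sweep(m, 2, model$mu), 2, model$sd, "/")
  f <- cvae_forward(model$params, m, rep(as.integer(y), nrow(m)),
                    eps_z = NULL)
  list(loglik = -sum(f$recon) - sum(f$kl),
       loglik_recon = -sum(f$recon),
       recon_per_roi = -colSums(f$recon_mat),
       n_frames = nrow(m))
}

#' Classify subjects by ensemble CVAE likelihood ratio
#'
#' Assigns each subject to \eqn{\arg\max_y \sum_k \log p_k(X|y)} (sum over
#' the ensemble models; equal class priors), where the per-frame
#' log-likelihood is bounded by the negative reconstruction error of the
#' trained model (the conditional KL term is a label-dependent constant of
#' the inference network, not of the data, and is excluded from the
#' classification score). Exact likelihood ties are broken toward the
#' control class, deterministically.
#'
#' @param models a \code{cvae_model} or list of them (the ensemble).
#' @param timeseries named list of subject frame sets.
#' @param truth optional logical/0-1 vector of true labels (patient =
#'   TRUE) aligned with \code{timeseries}; enables the report.
#' @return list with \code{predicted} (logical, patient = TRUE),
#'   \code{loglik_gap} (patient minus control, per subject) and, given
#'   \code{truth}, \code{measures} (accuracy, sensitivity, specificity).
#' @export
cvae_classify <- function(models, timeseries, truth = NULL) {
  if (inherits(models, "cvae_model")) models <- list(models)
  gap <- vapply(timeseries, function(x) {
    sum(vapply(models, function(m) {
      cvae_loglik(m, x, 1)$loglik_recon - cvae_loglik(m, x, 0)$loglik_recon
    }, numeric(1)))
  }, numeric(1))
  predicted <- gap > 0
  out <- list(predicted = predicted, loglik_gap = gap)
  if (!is.null(truth)) {
    truth <- as.logical(truth)
    out$measures <- c(accuracy = mean(predicted == truth),
                      sensitivity = if (any(truth)) mean(predicted[truth])
                                    else NA_real_,
                      specificity = if (any(!truth)) mean(!predicted[!truth])
                                    else NA_real_)
  }
  out
}

#' Per-ROI contribution weights of a classified subject
#'
#' \eqn{\mathcal{L}_i = \sum_j [\log p(x_j^{(i)}|y=c) -
#' \log p(x_j^{(i)}|y=1-c)]} over the subject's frames, given the correct
#' label \code{c}, using the factorised per-ROI reconstruction
#' log-densities. Large \eqn{\mathcal{L}_i} marks ROIs better explained
#' under the correct label, i.e. ROIs driving the classification.
#'
#' @param model a \code{cvae_model}.
#' @param x subject frames.
#' @param c_label the subject's correct label (0/1).
#' @return numeric vector of length n0.
#' @export
cvae_contribution_weights <- function(model, x, c_label) {
  c_label <- as.integer(c_label)
  cvae_loglik(model, x, c_label)$recon_per_roi -
    cvae_loglik(model, x, 1 - c_label)$recon_per_roi
}

#' Train-and-test CVAE validation on held-out subjects
#'
#' Trains an ensemble of \code{config$n_ensemble} models (different seeds)
#' on the training subjects and classifies the held-out subjects by
#' ensemble likelihood ratio.
#'
#' @param timeseries named list of all subjects' frames.
#' @param manifest full manifest.
#' @param train_ids,test_ids subject id vectors.
#' @param config a \code{\link{cvae_config}}.
#' @return list with \code{models}, \code{classification} (see
#'   \code{\link{cvae_classify}}) and \code{test_ids}.
#' @export
cvae_validate <- function(timeseries, manifest, train_ids, test_ids,
                          config) {
  train_man <- manifest[manifest$subject_id %in% train_ids, , drop = FALSE]
  models <- lapply(seq_len(config$n_ensemble), function(k) {
    cvae_train(timeseries[train_man$subject_id], train_man, config,
               seed = child_seed(config$seed, k))
  })
  truth <- manifest$group[match(test_ids, manifest$subject_id)] == "patient"
  cls <- cvae_classify(models, timeseries[test_ids], truth = truth)
  list(models = models, classification = cls, test_ids = test_ids)
}
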