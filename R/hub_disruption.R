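#' Hub Disruption Index for one subject
#'
#' Regresses, across ROIs, the difference between the subject's nodal
#' metric and the reference (control cohort) mean on the reference mean
#' itself. The OLS slope kappa is the Hub Disruption Index: negative kappa
#' means ROIs that are high on the metric in the reference ("hubs") lose
#' value in this subject while low ROIs gain.
#'
#' @param subject_profile numeric per-ROI metric vector.
#' @param reference_profiles list (or rows of a matrix) of per-ROI metric
#'   vectors for the reference cohort; must not contain the subject.
#' @return list with \code{kappa} (slope), \code{intercept},
#'   \code{reference_mean} and \code{difference} vectors.
#' @export
hdi <- function(subject_profile, reference_profiles) {
  if (is.list(reference_profiles)) {
    reference_profiles <- do.call(rbind, reference_profiles)
  }
  stopifnot(ncol(reference_profiles) == length(subject_profile))
  ref_mean <- colMeans(reference_profiles)
  if (sd(ref_mean) == 0) stop("reference means have zero variance")
  diffs <- subject_profile - ref_mean
  # closed-form OLS with intercept
  xc <- ref_mean - mean(ref_mean)
  kappa <- sum(xc * diffs) / sum(xc^2)
  list(kappa = kappa,
       intercept = mean(diffs) - kappa * mean(ref_mean),
       reference_mean = ref_mean,
       difference = diffs)
}

#' Cohort-level hub disruption with group comparison
#'
#' Computes each subject's HDI: patients against the full control cohort;
#' each control against the remaining controls (leave-one-out). Group
#' kappas are compared with a two-tailed two-sample Welch t-test.
#'
#' @param profiles named list of per-subject nodal metric vectors (one
#'   metric), names matching \code{manifest$subject_id}.
#' @param manifest data frame with \code{subject_id} and \code{group}
#'   (\code{"patient"} / \code{"control"}).
#' @return list with \code{kappas} (data frame subject_id, group, kappa)
#'   and \code{test} (t, df, p_value, mean_patient, mean_control,
#'   degenerate flag).
#' @export
cohort_hdi <- function(profiles, manifest) {
  stopifnot(all(manifest$subject_id %in% names(profiles)))
  controls <- manifest$subject_id[manifest$group == "control"]
  patients <- manifest$subject_id[manifest$group == "patient"]
  if (length(controls) < 3) stop("need at least 3 controls for a reference")
  if (length(patients) < 2) stop("each group needs at least 2 subjects")
  control_mat <- do.call(rbind, profiles[controls])
  kap <- c(
    vapply(patients, function(id) hdi(profiles[[id]], control_mat)$kappa,
           numeric(1)),
    vapply(controls, function(id) {
      hdi(profiles[[id]], control_mat[setdiff(controls, id), , drop = FALSE])$kappa
    }, numeric(1)))
  kdf <- data.frame(
    subject_id = c(patients, controls),
    group = c(rep("patient", length(patients)),
              rep("control", length(controls))),
    kappa = unname(kap), stringsAsFactors = FALSE)
  kp <- kdf$kappa[kdf$group == "patient"]
  kc <- kdf$kappa[kdf$group == "control"]
  degenerate <- sd(kp) == 0 && sd(kc) == 0
  test <- if (degenerate) {
    list(t = NA_real_, df = NA_real_, p_value = NA_real_,
         mean_patient = mean(kp), mean_control = mean(kc),
         degenerate = TRUE)
  } else {
    tt <- t.test(kp, kc, var.equal = FALSE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_patient = mean(kp),
         mean_control = mean(kc), degenerate = FALSE)
  }
  list(kappas = kdf, test = test)
}

#' Node-removal robustness of the HDI group comparison
#'
#' Recomputes \code{\link{cohort_hdi}} on a reduced ROI set: either with
#' the top 5\% of ROIs by control-reference mean removed, or with a random
#' 90\% of ROIs removed.
#'
#' @param profiles,manifest as in \code{\link{cohort_hdi}}.
#' @param mode \code{"drop_top_5pct"} or \code{"random_drop_90pct"}.
#' @param seed seed for the random mode.
#' @return as \code{\link{cohort_hdi}}, plus \code{kept_rois}.
#' @export
hdi_robustness <- function(profiles, manifest,
                           mode = c("drop_top_5pct", "random_drop_90pct"),
                           seed = 1L) {
  mode <- match.arg(mode)
  controls <- manifest$subject_id[manifest$group == "control"]
  ref_mean <- colMeans(do.call(rbind, profiles[controls]))
  n <- length(ref_mean)
  keep <- switch(mode,
    drop_top_5pct = {
      n_drop <- ceiling(0.05 * n)
      sort(order(ref_mean, decreasing = TRUE)[-seq_len(n_drop)])
    },
    random_drop_90pct = with_seed(seed, sort(sample.int(n, ceiling(0.1 * n)))))
  if (length(keep) < 10) stop("fewer than 10 ROIs would remain")
  red <- lapply(profiles, function(p) p[keep])
  out <- cohort_hdi(red, manifest)
  out$kept_rois <- keep
  out
}
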