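#' Specify a synthetic multi-site cohort
#'
#' Bundles the generative parameters for a synthetic resting-state cohort:
#' number of ROIs, per-site subject counts, frame counts and repetition
#' times, and the planted block-correlation structure. Sites mimic a
#' multi-centre acquisition: they differ in frame count, sampling interval
#' and a global variance scale.
#'
#' The signal model for ROI \eqn{i} in module \eqn{m} is
#' \deqn{x_i(t) = \sqrt{w - b}\, L_m(t) + \sqrt{b}\, G(t) + \sigma\,
#'   \epsilon_i(t)}
#' with per-module latent \eqn{L_m}, a global latent \eqn{G}, white noise
#' \eqn{\epsilon_i}, \eqn{w} = \code{within_module_corr} and \eqn{b} =
#' \code{between_module_corr}. With the default noise level
#' \eqn{\sigma = \sqrt{1 - w}} the population correlation is exactly
#' \eqn{w} for same-module pairs and \eqn{b} otherwise; a different
#' \code{noise_sd} rescales both by \eqn{(w + \sigma^2)^{-1}} toward 0.
#' All latents are white and every channel passes through the same
#' band-pass filter, so the instantaneous correlation structure survives
#' filtering.
#'
#' @param n_rois number of ROIs (atlas parcels).
#' @param n_subjects_per_group_per_site scalar or length-\code{n_sites}
#'   vector of subjects per group at each site.
#' @param n_sites number of acquisition sites.
#' @param n_frames integer vector (recycled to \code{n_sites}) of frames
#'   per site.
#' @param tr_seconds sampling interval per site, seconds.
#' @param site_scale global signal-amplitude multiplier per site.
#' @param within_module_corr,between_module_corr target Pearson
#'   correlations for same-module / different-module ROI pairs;
#'   \code{0 <= between < within < 1}.
#' @param noise_sd white-noise standard deviation; default
#'   \code{sqrt(1 - within_module_corr)} makes the targets exact.
#' @param bandpass logical; band-pass filter the generated series to
#'   0.008-0.1 Hz so synthetic data share the spectral support the
#'   pipeline assumes.
#' @param seed master seed for the cohort.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_rois = 140,
                        n_subjects_per_group_per_site = 27,
                        n_sites = 3,
                        n_frames = c(300L, 234L, 244L),
                        tr_seconds = c(2.0, 2.5, 2.5),
                        site_scale = c(1.0, 1.1, 0.9),
                        within_module_corr = 0.5,
                        between_module_corr = 0.05,
                        noise_sd = sqrt(1 - within_module_corr),
                        bandpass = TRUE,
                        seed = 1L) {
  stopifnot(n_rois >= 2, n_sites >= 1,
            between_module_corr >= 0,
            between_module_corr < within_module_corr,
            within_module_corr < 1,
            noise_sd >= 0)
  n_per <- rep_len(as.integer(n_subjects_per_group_per_site), n_sites)
  n_frames <- rep_len(as.integer(n_frames), n_sites)
  if (any(n_frames < 30)) {
    stop("n_frames too small to estimate correlations (minimum 30)")
  }
  structure(list(
    n_rois = as.integer(n_rois),
    n_subjects_per_group_per_site = n_per,
    n_sites = as.integer(n_sites),
    n_frames = n_frames,
    tr_seconds = rep_len(tr_seconds, n_sites),
    site_scale = rep_len(site_scale, n_sites),
    within_module_corr = within_module_corr,
    between_module_corr = between_module_corr,
    noise_sd = noise_sd,
    bandpass = bandpass,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Plant the ground truth of a synthetic cohort
#'
#' Draws a module partition of the ROIs, a set of reorganised nodes whose
#' module membership differs between the two groups (each moved to a
#' different existing module in the pain partition), a set of hubs that are
#' degraded in the pain group, and a set of class-signal nodes carrying a
#' covariance difference for the classifiers.
#'
#' Hubs are created by coupling the node to \code{n_hub_targets} extra
#' module latents at loading \code{hub_coupling} (control group); the pain
#' group multiplies that loading by \code{hub_attenuation}, so hubs lose
#' degree and centrality while the rest of the graph is untouched.
#' Class-signal nodes share an extra latent at loading
#' \code{class_coupling} in the pain group only.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param n_modules number of planted modules (>= 2).
#' @param n_reorganised number of nodes whose module differs between
#'   groups.
#' @param n_hubs number of planted (and, in patients, disrupted) hubs.
#' @param n_class_signal number of nodes carrying the classification
#'   signal.
#' @param hub_coupling,hub_attenuation,n_hub_targets,class_coupling
#'   effect-size parameters; see Details.
#' @return an object of class \code{ground_truth} with fields
#'   \code{partition_control}, \code{partition_pain},
#'   \code{reorganised_nodes}, \code{disrupted_hubs},
#'   \code{class_signal_nodes}, \code{hub_targets} and the effect sizes.
#' @export
make_ground_truth <- function(spec, n_modules = 10, n_reorganised = 6,
                              n_hubs = 6, n_class_signal = 10,
                              hub_coupling = 0.5, hub_attenuation = 0.3,
                              n_hub_targets = 3, class_coupling = 0.6) {
  stopifnot(inherits(spec, "cohort_spec"), n_modules >= 2)
  n <- spec$n_rois
  if (n_modules > n) stop("n_modules may not exceed the number of ROIs")
  if (n_reorganised + n_hubs > n) {
    stop("n_reorganised + n_hubs may not exceed the number of ROIs")
  }
  with_seed(spec$seed, {
    partition_control <- rep_len(seq_len(n_modules), n)
    special <- sample.int(n, n_reorganised + n_hubs + n_class_signal,
                          replace = FALSE)
    reorganised <- sort(special[seq_len(n_reorganised)])
    hubs <- sort(special[n_reorganised + seq_len(n_hubs)])
    class_nodes <- sort(special[n_reorganised + n_hubs +
                                  seq_len(n_class_signal)])
    partition_pain <- partition_control
    for (i in reorganised) {
      other <- setdiff(seq_len(n_modules), partition_control[i])
      partition_pain[i] <- if (length(other) == 1) other else sample(other, 1)
    }
    hub_targets <- lapply(hubs, function(i) {
      other <- setdiff(seq_len(n_modules), partition_control[i])
      k <- min(n_hub_targets, length(other))
      sort(sample(other, k))
    })
    names(hub_targets) <- as.character(hubs)
    structure(list(
      n_modules = as.integer(n_modules),
      partition_control = partition_control,
      partition_pain = partition_pain,
      reorganised_nodes = reorganised,
      disrupted_hubs = hubs,
      class_signal_nodes = class_nodes,
      hub_targets = hub_targets,
      hub_coupling = hub_coupling,
      hub_attenuation = hub_attenuation,
      class_coupling = class_coupling,
      effect_size = hub_coupling * (1 - hub_attenuation)
    ), class = "ground_truth")
  })
}

#' Simulate one subject's ROI time series
#'
#' Mixes per-module latent signals, a global latent and white noise
#' according to the group's planted partition (see
#' \code{\link{cohort_spec}} for the model), plants hub degradation and the
#' class-covariance signal for the pain group, applies the site's variance
#' scale, and (optionally) band-pass filters to 0.008-0.1 Hz.
#'
#' @param truth a \code{\link{make_ground_truth}} result.
#' @param spec a \code{\link{cohort_spec}}.
#' @param group \code{"control"} or \code{"pain"}.
#' @param subject_seed integer seed for this subject.
#' @param site site index in \code{1..n_sites}.
#' @return a \code{\link{roi_timeseries}}.
#' @export
simulate_subject_timeseries <- function(truth, spec, group = c("control", "pain"),
                                        subject_seed = 1L, site = 1L) {
  group <- match.arg(group)
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "cohort_spec"))
  site <- as.integer(site)
  stopifnot(site >= 1, site <= spec$n_sites)
  n <- spec$n_rois
  t_len <- spec$n_frames[site]
  if (t_len < 30) stop("n_frames too small to estimate correlations")
  part <- if (group == "pain") truth$partition_pain else truth$partition_control
  w <- spec$within_module_corr
  b <- spec$between_module_corr
  lam <- sqrt(w - b)
  mu <- sqrt(b)

  with_seed(subject_seed, {
    latents <- matrix(rnorm(t_len * truth$n_modules), t_len, truth$n_modules)
    global <- rnorm(t_len)
    class_latent <- rnorm(t_len)
    x <- latents[, part, drop = FALSE] * lam +
      outer(global, rep(mu, n)) +
      matrix(rnorm(t_len * n, sd = spec$noise_sd), t_len, n)
    # hubs couple to extra module latents; attenuated in the pain group
    hub_c <- truth$hub_coupling * lam
    if (group == "pain") hub_c <- hub_c * truth$hub_attenuation
    for (i in truth$disrupted_hubs) {
      tg <- truth$hub_targets[[as.character(i)]]
      if (length(tg)) {
        x[, i] <- x[, i] + rowSums(latents[, tg, drop = FALSE]) * hub_c
      }
    }
    # class-signal nodes share an extra latent in the pain group only
    if (group == "pain" && length(truth$class_signal_nodes)) {
      x[, truth$class_signal_nodes] <-
        x[, truth$class_signal_nodes] + truth$class_coupling * class_latent
    }
    x <- x * spec$site_scale[site]
    ts <- roi_timeseries(x, tr_seconds = spec$tr_seconds[site],
                         roi_labels = paste0("ROI", seq_len(n)))
    if (spec$bandpass) ts <- bandpass(ts) else ts
  })
}

#' Simulate a six-parameter rigid-body motion trace
#'
#' Produces a smooth low-amplitude random-walk drift in three translations
#' (mm) and three rotations (radians), with single-frame displacement
#' spikes of \code{spike_size_mm} inserted at \code{spike_frames}.
#'
#' @param n_frames number of frames.
#' @param spike_frames integer vector of frames (in \code{2..n_frames})
#'   receiving a displacement spike.
#' @param spike_size_mm spike amplitude, mm (applied to the x translation).
#' @param seed integer seed.
#' @param drift_sd per-frame standard deviation of the translation random
#'   walk, mm (rotations use \code{drift_sd / 50}).
#' @return a numeric matrix \code{n_frames x 6} (columns
#'   \code{trans_x..trans_z} in mm, \code{rot_x..rot_z} in radians).
#' @export
simulate_motion <- function(n_frames, spike_frames = integer(),
                            spike_size_mm = 1.0, seed = 1L,
                            drift_sd = 0.01) {
  stopifnot(n_frames >= 2)
  spike_frames <- as.integer(spike_frames)
  if (length(spike_frames) &&
      (any(spike_frames < 2) || any(spike_frames > n_frames))) {
    stop("spike_frames must lie in 2..n_frames")
  }
  with_seed(seed, {
    m <- cbind(
      apply(matrix(rnorm(n_frames * 3, sd = drift_sd), n_frames, 3), 2, cumsum),
      apply(matrix(rnorm(n_frames * 3, sd = drift_sd / 50), n_frames, 3),
            2, cumsum)
    )
    m[spike_frames, 1] <- m[spike_frames, 1] + spike_size_mm
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    m
  })
}

#' Simulate a complete multi-site cohort
#'
#' Generates every subject's time series and motion trace plus a manifest
#' (subject id, site, group, BDI score, gender). Per-subject seeds are
#' derived deterministically from the cohort seed, so the whole cohort is
#' reproducible bit-for-bit from \code{(spec, truth)}.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param truth a \code{\link{make_ground_truth}} result (or \code{NULL}
#'   to create one with default effect sizes).
#' @param motion logical; also simulate motion traces (a Poisson number of
#'   spikes per subject, ~1 per 75 frames, sizes 0.6-2 mm).
#' @return a list with \code{manifest} (data frame), \code{timeseries}
#'   (named list of \code{\link{roi_timeseries}}), \code{motion} (named
#'   list of matrices), \code{spec} and \code{truth}.
#' @export
simulate_cohort <- function(spec, truth = NULL, motion = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(truth)) truth <- make_ground_truth(spec)
  sites <- LETTERS[seq_len(spec$n_sites)]
  rows <- list()
  idx <- 0L
  for (s in seq_len(spec$n_sites)) {
    for (g in c("control", "pain")) {
      for (k in seq_len(spec$n_subjects_per_group_per_site[s])) {
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          subject_id = sprintf("S%03d", idx),
          site = sites[s], group = if (g == "pain") "patient" else "control",
          site_index = s, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  n_sub <- nrow(manifest)
  seeds <- (as.numeric(spec$seed) * 7919 + seq_len(n_sub) * 104729) %%
    2147483647
  manifest$subject_seed <- as.integer(seeds)
  with_seed(spec$seed + 1L, {
    manifest$bdi <- ifelse(manifest$group == "patient",
                           pmax(0, round(rnorm(n_sub, 13, 8))),
                           pmax(0, round(rnorm(n_sub, 3, 3))))
    manifest$gender <- sample(c("F", "M"), n_sub, replace = TRUE)
  })
  ts_list <- vector("list", n_sub)
  mo_list <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    s <- manifest$site_index[i]
    grp <- if (manifest$group[i] == "patient") "pain" else "control"
    ts_list[[i]] <- simulate_subject_timeseries(
      truth, spec, group = grp, subject_seed = manifest$subject_seed[i],
      site = s)
    if (motion) {
      nf <- spec$n_frames[s]
      mo_list[[i]] <- with_seed(manifest$subject_seed[i] + 1L, {
        n_spk <- rpois(1, nf / 75)
        frames <- if (n_spk > 0) sample(2:nf, min(n_spk, nf - 1)) else integer()
        sizes <- runif(1, 0.6, 2)
        simulate_motion(nf, spike_frames = frames, spike_size_mm = sizes,
                        seed = manifest$subject_seed[i] + 2L)
      })
    }
  }
  names(ts_list) <- manifest$subject_id
  if (motion) names(mo_list) <- manifest$subject_id
  list(manifest = manifest[, c("subject_id", "site", "group", "bdi",
                               "gender", "site_index", "subject_seed")],
       timeseries = ts_list,
       motion = if (motion) mo_list else NULL,
       spec = spec, truth = truth)
}

#' Write a synthetic cohort to tab-delimited files
#'
#' Writes one time-series file and one motion file per subject (one frame
#' per row; the time-series header row carries the ROI labels), the
#' manifest, and the ground truth as a key-value text file.
#'
#' @param cohort result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in cohort$manifest$subject_id) {
    ts <- cohort$timeseries[[id]]
    df <- as.data.frame(ts$data)
    names(df) <- ts$roi_labels
    write.table(df, file.path(dir, paste0(id, "_timeseries.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cohort$motion)) {
      write.table(as.data.frame(cohort$motion[[id]]),
                  file.path(dir, paste0(id, "_motion.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  tr <- cohort$truth
  kv <- c(
    paste0("n_modules=", tr$n_modules),
    paste0("partition_control=", paste(tr$partition_control, collapse = ",")),
    paste0("partition_pain=", paste(tr$partition_pain, collapse = ",")),
    paste0("reorganised_nodes=", paste(tr$reorganised_nodes, collapse = ",")),
    paste0("disrupted_hubs=", paste(tr$disrupted_hubs, collapse = ",")),
    paste0("class_signal_nodes=", paste(tr$class_signal_nodes, collapse = ",")),
    paste0("effect_size=", tr$effect_size))
  writeLines(kv, file.path(dir, "ground_truth.txt"))
  invisible(dir)
}

#' Read a subject time-series file written by \code{\link{write_cohort}}
#' @param path file path.
#' @param tr_seconds sampling interval to attach.
#' @return a \code{\link{roi_timeseries}}.
#' @export
read_timeseries <- function(path, tr_seconds) {
  df <- read.delim(path, check.names = FALSE)
  roi_timeseries(as.matrix(df), tr_seconds = tr_seconds,
                 roi_labels = names(df))
}
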