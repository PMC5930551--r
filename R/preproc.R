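#' ROI time-series container
#'
#' A frames x ROIs signal matrix with its sampling interval and unique ROI
#' labels; the unit of all temporal preprocessing.
#'
#' @param data numeric matrix, frames x ROIs, no missing values.
#' @param tr_seconds sampling interval (repetition time), seconds.
#' @param roi_labels character vector of unique ROI names.
#' @return an object of class \code{roi_timeseries}.
#' @export
roi_timeseries <- function(data, tr_seconds, roi_labels = colnames(data)) {
  data <- as.matrix(data)
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(ncol(data)))
  stopifnot(nrow(data) >= 2, !anyNA(data), all(is.finite(data)),
            tr_seconds > 0, length(roi_labels) == ncol(data),
            !anyDuplicated(roi_labels))
  colnames(data) <- roi_labels
  structure(list(data = data, tr_seconds = tr_seconds,
                 roi_labels = roi_labels),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d frames x %d ROIs, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' FD at frame \eqn{j} is the sum of the absolute frame-to-frame changes of
#' the three translations (mm) plus the three rotations converted to arc
#' length on a sphere of \code{head_radius_mm}:
#' \eqn{FD_j = \sum |\Delta d| + r \sum |\Delta \theta|}; the first frame
#' has FD 0 by convention.
#'
#' @param motion numeric matrix, frames x 6 (translations mm, rotations
#'   radians).
#' @param head_radius_mm rotation-to-displacement conversion radius
#'   (default 50 mm, the standard for motion scrubbing).
#' @return numeric vector of per-frame FD, mm.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) >= 2, ncol(motion) == 6)
  if (!all(is.finite(motion))) stop("motion parameters contain non-finite values")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion scrubbing mask
#'
#' Flags every frame whose framewise displacement exceeds
#' \code{threshold_mm}, and censors it together with the \code{n_back}
#' previous and \code{n_forward} following frames (windows clipped at the
#' series ends, union over offending frames).
#'
#' @param fd per-frame FD (mm), as from \code{\link{framewise_displacement}}.
#' @param threshold_mm censoring threshold (default 0.5 mm).
#' @param n_back,n_forward window extent around each offending frame.
#' @return logical frame mask, \code{TRUE} = retained.
#' @export
scrub <- function(fd, threshold_mm = 0.5, n_back = 1, n_forward = 2) {
  stopifnot(threshold_mm > 0, n_back >= 0, n_forward >= 0)
  n <- length(fd)
  keep <- rep(TRUE, n)
  for (j in which(fd > threshold_mm)) {
    keep[max(1, j - n_back):min(n, j + n_forward)] <- FALSE
  }
  keep
}

#' DVARS: root-mean-square frame-to-frame signal change
#'
#' \code{dvars(ts)[j]} is the RMS over ROIs of the signal change from frame
#' \eqn{j-1} to \eqn{j}; the first frame is 0 by convention.
#'
#' @param ts a \code{\link{roi_timeseries}}.
#' @return numeric vector of per-frame DVARS.
#' @export
dvars <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  d <- diff(ts$data)
  c(0, sqrt(rowMeans(d^2)))
}

#' Interquartile-range subject exclusion on summary DVARS
#'
#' Excludes subjects whose post-scrub mean DVARS lies more than three
#' interquartile ranges above the upper quartile or below the lower
#' quartile. Quartiles use the linear-interpolation convention
#' (\code{quantile} type 7); when the IQR is 0 only exact equality with the
#' common value passes.
#'
#' @param summaries named numeric vector of per-subject mean DVARS.
#' @param n_iqr fence width in IQR units (default 3).
#' @return character vector of excluded subject names (possibly empty).
#' @export
dvars_exclusion <- function(summaries, n_iqr = 3) {
  stopifnot(length(summaries) >= 4, all(is.finite(summaries)))
  q <- quantile(summaries, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  bad <- summaries < q[1] - n_iqr * iqr | summaries > q[2] + n_iqr * iqr
  names(summaries)[bad]
}

#' Zero-phase band-pass filter
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (zero phase), with the fMRI default transmission band 0.008-0.1 Hz.
#' The per-ROI mean (DC) is removed by construction.
#'
#' @param ts a \code{\link{roi_timeseries}}.
#' @param low_hz,high_hz band edges; \code{high_hz} must be below the
#'   Nyquist frequency \code{1 / (2 tr_seconds)}.
#' @return a filtered \code{\link{roi_timeseries}}.
#' @export
bandpass <- function(ts, low_hz = 0.008, high_hz = 0.1) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (high_hz <= low_hz) stop("high_hz must exceed low_hz")
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (high_hz >= nyquist) stop("high_hz must be below the Nyquist frequency")
  bf <- signal::butter(2, c(low_hz, high_hz) / nyquist, type = "pass")
  centred <- sweep(ts$data, 2, colMeans(ts$data))
  filtered <- .filtfilt_cpp(bf$b, bf$a, centred)
  roi_timeseries(filtered, ts$tr_seconds, ts$roi_labels)
}

#' Nuisance regression
#'
#' Regresses the given confound time courses (e.g. the six motion
#' parameters and a global-signal regressor, plus an intercept) out of
#' every ROI, returning least-squares residuals orthogonal to every
#' regressor column. Rank-deficient regressor sets are handled by dropping
#' aliased columns (with a message).
#'
#' @param ts a \code{\link{roi_timeseries}}.
#' @param regressors numeric matrix, frames x k, including an intercept
#'   column (one is appended if absent).
#' @return residual \code{\link{roi_timeseries}}.
#' @export
nuisance_regress <- function(ts, regressors) {
  stopifnot(inherits(ts, "roi_timeseries"))
  X <- as.matrix(regressors)
  stopifnot(nrow(X) == nrow(ts$data))
  has_intercept <- any(apply(X, 2, function(c) sd(c) == 0 & c[1] != 0))
  if (!has_intercept) X <- cbind(intercept = 1, X)
  if (ncol(X) >= nrow(X)) stop("more regressors than frames")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    message("nuisance_regress: dropping ", length(dropped),
            " rank-deficient regressor column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  resid <- ts$data - X %*% qr.coef(qrX, ts$data)
  roi_timeseries(resid, ts$tr_seconds, ts$roi_labels)
}

#' Full temporal preprocessing for one subject
#'
#' Fixed, logged order: band-pass filter the full series, regress out the
#' nuisance set (six motion parameters + global signal + intercept),
#' compute FD and the scrubbing mask, and compute DVARS on the analysed
#' (filtered, regressed) series. The mask is applied later, at correlation
#' time; DVARS summaries are taken over retained frames ("after the
#' scrubbing").
#'
#' @param ts a \code{\link{roi_timeseries}}.
#' @param motion frames x 6 motion-parameter matrix.
#' @param fd_threshold_mm scrubbing threshold (default 0.5 mm).
#' @param low_hz,high_hz band-pass edges.
#' @return list with the processed \code{ts}, logical \code{mask},
#'   \code{fd}, \code{dvars}, and scalar QC summaries \code{mean_fd},
#'   \code{retained_fraction}, \code{mean_dvars}.
#' @export
preprocess_subject <- function(ts, motion, fd_threshold_mm = 0.5,
                               low_hz = 0.008, high_hz = 0.1) {
  stopifnot(inherits(ts, "roi_timeseries"), nrow(motion) == nrow(ts$data))
  filtered <- bandpass(ts, low_hz, high_hz)
  nuis <- cbind(as.matrix(motion), global = rowMeans(filtered$data))
  cleaned <- nuisance_regress(filtered, nuis)
  fd <- framewise_displacement(motion)
  mask <- scrub(fd, threshold_mm = fd_threshold_mm)
  dv <- dvars(cleaned)
  list(ts = cleaned, mask = mask, fd = fd, dvars = dv,
       mean_fd = mean(fd[mask]),
       retained_fraction = mean(mask),
       mean_dvars = mean(dv[mask]))
}

#' Preprocess a whole cohort and build the QC table
#'
#' Runs \code{\link{preprocess_subject}} on every subject, then applies the
#' interquartile-range exclusion rule to the post-scrub mean DVARS
#' summaries.
#'
#' @param cohort a \code{\link{simulate_cohort}}-shaped list (fields
#'   \code{manifest}, \code{timeseries}, \code{motion}).
#' @param ... passed to \code{\link{preprocess_subject}}.
#' @return list with \code{subjects} (named list of per-subject results)
#'   and \code{qc} (data frame: subject_id, mean_fd, retained_fraction,
#'   mean_dvars, excluded_flag).
#' @export
preprocess_cohort <- function(cohort, ...) {
  ids <- cohort$manifest$subject_id
  subjects <- lapply(ids, function(id) {
    preprocess_subject(cohort$timeseries[[id]], cohort$motion[[id]], ...)
  })
  names(subjects) <- ids
  dv <- vapply(subjects, function(s) s$mean_dvars, numeric(1))
  excluded <- dvars_exclusion(dv)
  qc <- data.frame(
    subject_id = ids,
    mean_fd = vapply(subjects, function(s) s$mean_fd, numeric(1)),
    retained_fraction = vapply(subjects, function(s) s$retained_fraction,
                               numeric(1)),
    mean_dvars = dv,
    excluded_flag = ids %in% excluded,
    row.names = NULL, stringsAsFactors = FALSE)
  list(subjects = subjects, qc = qc)
}
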