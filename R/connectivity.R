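#' Pearson correlation matrix over retained frames
#'
#' Computes the full ROI x ROI Pearson correlation matrix of a subject's
#' time series, restricted to the frames retained by the scrubbing mask.
#'
#' @param ts a \code{\link{roi_timeseries}}.
#' @param mask logical frame mask (default: all frames retained).
#' @return symmetric correlation matrix with unit diagonal, ROI labels as
#'   dimnames.
#' @export
correlation_matrix <- function(ts, mask = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$data
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(x), is.logical(mask))
    x <- x[mask, , drop = FALSE]
  }
  if (nrow(x) < 3) stop("fewer than 3 retained frames")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI(s): ",
         paste(ts$roi_labels[sds == 0], collapse = ", "))
  }
  r <- cor(x)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(ts$roi_labels, ts$roi_labels)
  r
}

#' Fisher z-transform
#'
#' \eqn{z = \mathrm{atanh}(r)}; variance-stabilises Pearson correlations.
#'
#' @param r correlation value(s), \eqn{|r| < 1}.
#' @return transformed values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("|r| must be < 1 for fisher_z")
  atanh(r)
}

#' Threshold a correlation matrix to a fixed link density
#'
#' Keeps exactly \code{floor(density * n(n-1)/2)} strongest off-diagonal
#' entries by signed correlation value and binarises. Ties at the cut are
#' broken lexicographically on the (row, column) upper-triangle index, so
#' the edge count is exact and platform-independent. Being rank-based, the
#' result is invariant to any strictly monotone transform of the values
#' (e.g. Fisher z).
#'
#' @param c_mat symmetric correlation (or weight) matrix.
#' @param density target link density in (0, 1].
#' @return binary adjacency matrix (0/1) with zero diagonal and attribute
#'   \code{link_density}.
#' @export
threshold_to_density <- function(c_mat, density = 0.10) {
  stopifnot(is.matrix(c_mat), nrow(c_mat) == ncol(c_mat),
            density > 0, density <= 1)
  n <- nrow(c_mat)
  n_edges <- floor(density * n * (n - 1) / 2)
  ut <- which(upper.tri(c_mat))
  vals <- c_mat[ut]
  # order() is stable for ties via the secondary index key
  keep <- ut[order(-vals, ut)[seq_len(n_edges)]]
  a <- matrix(0L, n, n)
  a[keep] <- 1L
  a <- a + t(a)
  dimnames(a) <- dimnames(c_mat)
  attr(a, "link_density") <- density
  a
}

#' Upper-triangle Fisher-z feature vector
#'
#' Flattens a correlation matrix into the classifier feature vector: the
#' \eqn{n(n-1)/2} upper-triangle entries, Fisher z-transformed, in a
#' consistent (column-major upper-triangle) order.
#'
#' @param c_mat symmetric correlation matrix.
#' @param clip correlations with \eqn{|r| \ge 1} are clipped to
#'   \code{1 - 1e-7} before the transform.
#' @return named numeric vector of features ("ROIi|ROIj").
#' @export
connectivity_features <- function(c_mat, clip = TRUE) {
  n <- nrow(c_mat)
  ut <- upper.tri(c_mat)
  r <- c_mat[ut]
  if (clip) r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  z <- fisher_z(r)
  labs <- dimnames(c_mat)[[1]]
  if (!is.null(labs)) {
    idx <- which(ut, arr.ind = TRUE)
    names(z) <- paste(labs[idx[, 1]], labs[idx[, 2]], sep = "|")
  }
  z
}

#' Export a binary adjacency matrix as an edge list
#' @param a adjacency matrix from \code{\link{threshold_to_density}}.
#' @return data frame (i, j, weight) over the upper triangle.
#' @export
adjacency_edgelist <- function(a) {
  idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], weight = 1L)
}
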