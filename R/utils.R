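#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state, so seeded package internals
#' never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Derive a child seed from a master seed and a stream index by integer
# hashing (stays below 2^31, so always a valid R seed). Hash-based
# derivation keeps the streams of nearby (seed, index) pairs uncorrelated.
child_seed <- function(seed, index) {
  as.integer(.hash_seed_cpp(as.numeric(seed) %% 2147483647,
                            as.numeric(index) %% 2147483647))
}

#' Write a square matrix as a tab-delimited table with ROI labels
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  if (is.null(rownames(m))) {
    dimnames(m) <- list(paste0("ROI", seq_len(nrow(m))),
                        paste0("ROI", seq_len(ncol(m))))
  }
  df <- data.frame(roi = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square matrix written by \code{\link{write_matrix_tsv}}
#' @param path input path.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
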