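#' Nodal graph metrics of a binary undirected graph
#'
#' Computes one of the eight per-node metrics screened for hub disruption,
#' on a binary adjacency matrix:
#' \describe{
#'   \item{degree}{neighbour count.}
#'   \item{clustering_coefficient}{fraction of neighbour pairs that are
#'     directly linked (0 for degree < 2).}
#'   \item{betweenness_centrality}{number of shortest paths through the
#'     node (unnormalised; each unordered pair counted once; per component
#'     on disconnected graphs).}
#'   \item{eigenvector_centrality}{entry of the principal eigenvector of
#'     the adjacency matrix, non-negative and scaled to unit Euclidean
#'     norm; computed on the largest connected component, 0 elsewhere.}
#'   \item{k_coreness}{largest k such that the node belongs to the k-core.}
#'   \item{flow_coefficient}{fraction of neighbour pairs \emph{not}
#'     directly linked, i.e. whose local length-2 path must flow through
#'     the node (0 for degree < 2).}
#'   \item{local_efficiency}{efficiency (mean inverse shortest-path
#'     length) of the subgraph induced by the node's neighbours.}
#'   \item{participation_coefficient}{\eqn{1 - \sum_m (k_{im}/k_i)^2} over
#'     modules m of a community map (0 for isolated nodes).}
#' }
#'
#' @param a binary symmetric adjacency matrix, zero diagonal.
#' @param metric_name one of the eight names above.
#' @param community integer module label per node; required for the
#'   participation coefficient. If missing there, a single-slice
#'   modularity partition of \code{a} at resolution 1 is used.
#' @return numeric vector of per-node values.
#' @export
nodal_metric <- function(a,
                         metric_name = c("degree", "clustering_coefficient",
                                         "betweenness_centrality",
                                         "eigenvector_centrality",
                                         "k_coreness", "flow_coefficient",
                                         "local_efficiency",
                                         "participation_coefficient"),
                         community = NULL) {
  metric_name <- match.arg(metric_name)
  a <- unname(as.matrix(a)) * 1L
  stopifnot(nrow(a) == ncol(a), all(a %in% c(0L, 1L)),
            all(diag(a) == 0), isTRUE(all.equal(a, t(a))))
  n <- nrow(a)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  deg <- rowSums(a)
  out <- switch(metric_name,
    degree = deg,
    clustering_coefficient = {
      cc <- igraph::transitivity(g, type = "localundirected")
      cc[!is.finite(cc)] <- 0
      cc
    },
    betweenness_centrality = igraph::betweenness(g, directed = FALSE,
                                                 normalized = FALSE),
    eigenvector_centrality = eigenvector_largest_component(a),
    k_coreness = igraph::coreness(g),
    flow_coefficient = vapply(seq_len(n), function(v) {
      k <- deg[v]
      if (k < 2) return(0)
      nb <- which(a[v, ] == 1)
      1 - sum(a[nb, nb]) / (k * (k - 1))
    }, numeric(1)),
    local_efficiency = vapply(seq_len(n), function(v) {
      nb <- which(a[v, ] == 1)
      k <- length(nb)
      if (k < 2) return(0)
      d <- igraph::distances(igraph::induced_subgraph(g, nb))
      inv <- 1 / d[upper.tri(d)]
      inv[!is.finite(inv)] <- 0
      2 * sum(inv) / (k * (k - 1))
    }, numeric(1)),
    participation_coefficient = {
      if (is.null(community)) {
        community <- single_slice_partition(a, gamma = 1, seed = 1L)
      }
      stopifnot(length(community) == n)
      vapply(seq_len(n), function(v) {
        if (deg[v] == 0) return(0)
        k_im <- tapply(a[v, ], community, sum)
        1 - sum((k_im / deg[v])^2)
      }, numeric(1))
    })
  out <- unname(as.numeric(out))
  out
}

# Principal eigenvector of the largest connected component, entries made
# non-negative and scaled to unit Euclidean norm; zeros off-component.
eigenvector_largest_component <- function(a) {
  n <- nrow(a)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  comp <- igraph::components(g)
  big <- which(comp$membership == which.max(comp$csize))
  v <- numeric(n)
  if (length(big) == 1) {
    v[big] <- 1
    return(v)
  }
  sub <- a[big, big, drop = FALSE]
  ev <- eigen(sub, symmetric = TRUE)
  vec <- ev$vectors[, 1]
  if (sum(vec) < 0) vec <- -vec
  vec <- abs(vec)
  v[big] <- vec / sqrt(sum(vec^2))
  v
}

#' All eight nodal metrics for one adjacency matrix
#' @param a binary adjacency matrix.
#' @param community optional community map for the participation
#'   coefficient.
#' @return matrix, nodes x metrics.
#' @export
nodal_metric_profile <- function(a, community = NULL) {
  metrics <- c("degree", "clustering_coefficient", "betweenness_centrality",
               "eigenvector_centrality", "k_coreness", "flow_coefficient",
               "local_efficiency", "participation_coefficient")
  sapply(metrics, function(m) nodal_metric(a, m, community = community))
}
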