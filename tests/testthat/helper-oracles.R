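# Brute-force oracles, independent of the package's implementation paths:
# metrics via explicit enumeration (BFS, triangle counts, matrix powers),
# modularity via the literal double/quadruple sum.

# --- graph builders --------------------------------------------------------

graph_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (k in seq_len(nrow(edges))) {
    a[edges[k, 1], edges[k, 2]] <- 1L
    a[edges[k, 2], edges[k, 1]] <- 1L
  }
  a
}

# all labelled graphs on n nodes (n <= 5), as adjacency matrices
all_labelled_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(0:(2^m - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    a <- matrix(0L, n, n)
    on <- which(bits == 1)
    for (k in on) {
      a[pairs[k, 1], pairs[k, 2]] <- 1L
      a[pairs[k, 2], pairs[k, 1]] <- 1L
    }
    a
  })
}

random_connected_graph <- function(n, p = 0.4) {
  repeat {
    a <- matrix(0L, n, n)
    ut <- which(upper.tri(a))
    a[ut] <- rbinom(length(ut), 1, p)
    a <- a + t(a)
    if (oracle_is_connected(a)) return(a)
  }
}

oracle_is_connected <- function(a) {
  n <- nrow(a)
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1
  while (length(frontier)) {
    nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

oracle_components <- function(a) {
  n <- nrow(a)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

# --- nodal metric oracles --------------------------------------------------

oracle_degree <- function(a) rowSums(a)

oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / (k * (k - 1))
  }, numeric(1))
}

oracle_flow <- function(a) 1 * (oracle_degree(a) >= 2) -
  ifelse(oracle_degree(a) >= 2, oracle_clustering(a), 0)

# BFS shortest-path distances and path counts from one source
bfs_paths <- function(a, s) {
  n <- nrow(a)
  dist <- rep(Inf, n); cnt <- rep(0, n)
  dist[s] <- 0; cnt[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(a[v, ] == 1)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) cnt[w] <- cnt[w] + cnt[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, cnt = cnt)
}

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) d[s, ] <- bfs_paths(a, s)$dist
  d
}

# betweenness by explicit enumeration over source-target pairs:
# sigma_st(v) / sigma_st, each unordered pair counted once
oracle_betweenness <- function(a) {
  n <- nrow(a)
  bfs <- lapply(seq_len(n), function(s) bfs_paths(a, s))
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(bfs[[s]]$dist[t])) next
      sig_st <- bfs[[s]]$cnt[t]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == bfs[[s]]$dist[t]) {
          btw[v] <- btw[v] + bfs[[s]]$cnt[v] * bfs[[t]]$cnt[v] / sig_st
        }
      }
    }
  }
  btw
}

# eigenvector centrality by power iteration on the largest component
oracle_eigenvector <- function(a) {
  n <- nrow(a)
  comp <- oracle_components(a)
  sizes <- tabulate(comp)
  big <- which(comp == which.max(sizes))
  v <- numeric(n)
  if (length(big) == 1 || sum(a[big, big]) == 0) {
    v[big[1]] <- 1
    if (length(big) > 1) v[big] <- 1 / sqrt(length(big))
    return(v)
  }
  sub <- a[big, big]
  x <- rep(1, length(big))
  for (it in 1:10000) {
    # shifted iteration (A + I): same eigenvector, no bipartite oscillation
    x_new <- as.numeric(sub %*% x) + x
    x_new <- x_new / sqrt(sum(x_new^2))
    if (max(abs(x_new - x)) < 1e-12) { x <- x_new; break }
    x <- x_new
  }
  v[big] <- abs(x)
  v
}

# k-coreness by iterative peeling
oracle_kcore <- function(a) {
  n <- nrow(a)
  core <- rep(0L, n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- rowSums(a[, alive, drop = FALSE]) * alive
      peel <- which(alive & deg <= k)
      if (!length(peel)) break
      core[peel] <- k
      alive[peel] <- FALSE
    }
    k <- k + 1L
  }
  core
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    d <- oracle_distances(a[nb, nb, drop = FALSE])
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    2 * sum(inv) / (k * (k - 1))
  }, numeric(1))
}

oracle_participation <- function(a, community) {
  n <- nrow(a)
  deg <- rowSums(a)
  vapply(seq_len(n), function(v) {
    if (deg[v] == 0) return(0)
    s <- 0
    for (m in unique(community)) {
      k_im <- sum(a[v, community == m])
      s <- s + (k_im / deg[v])^2
    }
    1 - s
  }, numeric(1))
}

# --- modularity oracles ----------------------------------------------------

# Newman-Girvan modularity with resolution gamma, literal double sum
oracle_newman_girvan <- function(a, labels, gamma = 1) {
  k <- rowSums(a)
  twom <- sum(k)
  if (twom == 0) return(0)
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) {
        q <- q + a[i, j] - gamma * k[i] * k[j] / twom
      }
    }
  }
  q / twom
}

# categorical multislice modularity, literal quadruple sum over (i,j,s,r)
oracle_multislice <- function(adjacencies, partition, gamma, omega) {
  n <- nrow(adjacencies[[1]])
  S <- length(adjacencies)
  k <- sapply(adjacencies, rowSums)          # n x S
  twom <- colSums(k)
  q <- 0
  for (s in seq_len(S)) {
    for (r in seq_len(S)) {
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (partition[i, s] != partition[j, r]) next
          if (s == r) {
            null <- if (twom[s] > 0) gamma * k[i, s] * k[j, s] / twom[s] else 0
            q <- q + adjacencies[[s]][i, j] - null
          } else if (i == j) {
            q <- q + omega
          }
        }
      }
    }
  }
  twomu <- sum(twom) + omega * n * S * (S - 1)
  if (twomu == 0) 0 else q / twomu
}

# scrub window-union oracle: literal enumeration
oracle_scrub <- function(fd, threshold = 0.5, n_back = 1, n_forward = 2) {
  n <- length(fd)
  removed <- integer(0)
  for (j in seq_len(n)) {
    if (fd[j] > threshold) {
      removed <- union(removed, max(1, j - n_back):min(n, j + n_forward))
    }
  }
  keep <- rep(TRUE, n)
  keep[removed] <- FALSE
  keep
}

# closed-form OLS slope/intercept from the normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}
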