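# Independent brute-force oracles for graph measures, deliberately naive and
# separate from the package's (igraph-backed) implementations.

random_digraph_adj <- function(n, p = 0.15) {
  a <- matrix(runif(n * n) < p, n, n)
  diag(a) <- FALSE
  storage.mode(a) <- "numeric"
  a
}

adj_to_igraph <- function(adj, directed = TRUE) {
  igraph::graph_from_adjacency_matrix(adj, mode = if (directed) "directed"
                                                  else "undirected")
}

# Floyd-Warshall all-pairs shortest paths
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

bf_asl_diameter <- function(adj_und) {
  d <- bf_distances(adj_und)
  finite <- d[is.finite(d) & d > 0]
  list(asl = mean(finite), diameter = max(finite))
}

# SCC partition from pairwise reachability (transitive closure)
bf_scc_sizes <- function(adj) {
  n <- nrow(adj)
  r <- diag(n) + adj > 0
  for (k in seq_len(n))
    r <- r | (outer(r[, k], r[k, ], "&"))
  same <- r & t(r)
  seen <- rep(FALSE, n)
  sizes <- integer(0)
  for (v in seq_len(n)) {
    if (seen[v]) next
    comp <- which(same[v, ])
    seen[comp] <- TRUE
    sizes <- c(sizes, length(comp))
  }
  sort(sizes, decreasing = TRUE)
}

# Betweenness by shortest-path counting with adjacency-matrix powers:
# sigma_st = (A^d(s,t))[s,t]; sigma_st(v) = (A^d1)[s,v] * (A^d2)[v,t].
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  maxd <- max(d[is.finite(d)])
  pows <- vector("list", max(maxd, 1))
  p <- adj
  pows[[1]] <- p
  if (maxd >= 2) for (k in 2:maxd) { p <- p %*% adj; pows[[k]] <- p }
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(d[s, t]) || d[s, t] < 2) next
    dist <- d[s, t]
    sigma <- pows[[dist]][s, t]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      d1 <- d[s, v]; d2 <- d[v, t]
      if (is.finite(d1) && is.finite(d2) && d1 + d2 == dist && d1 >= 1)
        bc[v] <- bc[v] + pows[[d1]][s, v] * pows[[d2]][v, t] / sigma
    }
  }
  bc
}

# Global transitivity from triplet counts on an undirected adjacency matrix
bf_transitivity <- function(adj_und) {
  closed <- sum(diag(adj_und %*% adj_und %*% adj_und))  # 6 x triangles
  deg <- rowSums(adj_und)
  open <- sum(deg * (deg - 1))  # 2 x connected triplets
  if (open == 0) return(0)
  closed / open
}

# Edge-wise degree-degree Pearson correlation from the raw sums
bf_edge_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  if (den == 0) return(NA_real_)
  num / den
}

bf_assortativity_profile <- function(adj) {
  idx <- which(adj > 0, arr.ind = TRUE)
  din <- colSums(adj)
  dout <- rowSums(adj)
  list(r_in_in = bf_edge_pearson(din[idx[, 1]], din[idx[, 2]]),
       r_in_out = bf_edge_pearson(din[idx[, 1]], dout[idx[, 2]]),
       r_out_in = bf_edge_pearson(dout[idx[, 1]], din[idx[, 2]]),
       r_out_out = bf_edge_pearson(dout[idx[, 1]], dout[idx[, 2]]))
}

# Exhaustive window rescoring oracle for the target scan
bf_scan <- function(mirna, transcript, cutoff) {
  L <- nchar(mirna)
  res <- data.frame(start = integer(), expectation = numeric())
  for (w in seq_len(nchar(transcript) - L + 1)) {
    e <- score_duplex(mirna, substr(transcript, w, w + L - 1))$expectation
    if (e <= cutoff)
      res <- rbind(res, data.frame(start = w, expectation = e))
  }
  res
}

# Independent re-statement of the five cleavage-category rules
bf_category <- function(profile, pos) {
  t <- if (as.character(pos) %in% names(profile))
    unname(profile[as.character(pos)]) else 0
  m <- if (length(profile)) max(profile) else 0
  med <- if (length(profile)) median(profile) else NA
  u <- sum(profile == m)
  fired <- c(cat0 = t > 1 && t == m && u == 1,
             cat1 = t > 1 && t == m && u > 1,
             cat2 = t > 1 && t < m && t > med,
             cat3 = t > 1 && t < m && t <= med,
             cat4 = t == 1)
  list(fired = fired,
       category = if (t == 0) NA_integer_
                  else as.integer(which(fired) - 1L))
}

random_profile <- function(len = 60, p_occupied = 0.3, max_count = 6) {
  occ <- which(runif(len) < p_occupied)
  prof <- sample.int(max_count, length(occ), replace = TRUE)
  names(prof) <- occ
  prof
}
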