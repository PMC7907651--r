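#' Generate a reference graph for metric validation
#'
#' Produces the standard baseline families used to sanity-check network
#' measures: Erdos-Renyi random digraphs, preferential-attachment scale-free
#' digraphs, ring lattices and rewired (Watts-Strogatz) lattices. Lattice
#' graphs are returned as mutually directed edges so every family yields a
#' simple directed graph; their undirected projection is the classical
#' lattice / small-world graph.
#'
#' @param kind one of `"erdos_renyi"`, `"scale_free"`, `"ring_lattice"`,
#'   `"rewired_lattice"`.
#' @param n number of nodes (`>= 2`).
#' @param m_or_p for `erdos_renyi`: edge count (values `>= 1`) or edge
#'   probability (values `< 1`); for `scale_free`: edges added per node.
#' @param seed RNG seed.
#' @param k even neighbor count for the lattice families.
#' @param p_rewire rewiring probability for `rewired_lattice`.
#' @return an [igraph::igraph] directed graph.
#' @export
generate_reference_graph <- function(kind = c("erdos_renyi", "scale_free",
                                              "ring_lattice",
                                              "rewired_lattice"),
                                     n, m_or_p = NULL, seed = 1L, k = 4L,
                                     p_rewire = 0.05) {
  kind <- match.arg(kind)
  if (n < 2) stop("n must be >= 2")
  set.seed(seed)
  g <- switch(kind,
    erdos_renyi = {
      if (is.null(m_or_p)) stop("erdos_renyi needs m_or_p")
      if (m_or_p >= 1) {
        if (m_or_p > n * (n - 1))
          stop("infeasible: m exceeds n(n-1) directed edges")
        igraph::sample_gnm(n, m_or_p, directed = TRUE)
      } else {
        igraph::sample_gnp(n, m_or_p, directed = TRUE)
      }
    },
    scale_free = {
      m_per <- if (is.null(m_or_p)) 3L else max(1L, round(m_or_p))
      igraph::sample_pa(n, power = 1, m = m_per, directed = TRUE)
    },
    ring_lattice = {
      if (k %% 2 != 0) stop("lattice neighbor count k must be even")
      igraph::as_directed(
        igraph::sample_smallworld(1, n, nei = k / 2, p = 0),
        mode = "mutual")
    },
    rewired_lattice = {
      if (k %% 2 != 0) stop("lattice neighbor count k must be even")
      igraph::as_directed(
        igraph::sample_smallworld(1, n, nei = k / 2, p = p_rewire),
        mode = "mutual")
    })
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Sample from a discrete power-law distribution
#'
#' Inverse-CDF sampling from `P(X = k) \\propto k^-alpha` for
#' `k = xmin, ..., kmax`. The truncation mass above `kmax` is negligible for
#' the defaults.
#'
#' @param n sample size.
#' @param alpha exponent (`> 1`).
#' @param xmin minimum value.
#' @param kmax truncation point.
#' @return integer vector of length `n`.
#' @export
rpowerlaw <- function(n, alpha = 2.5, xmin = 1L, kmax = 1e6L) {
  if (alpha <= 1) stop("alpha must be > 1")
  k <- seq.int(xmin, kmax)
  cdf <- cumsum(k^(-alpha))
  cdf <- cdf / cdf[length(cdf)]
  k[findInterval(stats::runif(n), cdf) + 1L]
}
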