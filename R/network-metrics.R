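as_graph <- function(net) {
  if (inherits(net, "reg_network")) as_igraph(net)
  else if (igraph::is_igraph(net)) net
  else stop("expected a reg_network or igraph object")
}

undirected_projection <- function(g) {
  igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
}

# Hurwitz zeta sum_{k>=q} k^-a via direct summation plus an Euler-Maclaurin
# tail correction; accurate to ~1e-10 for a > 1.
hurwitz_zeta <- function(a, q, n_direct = 2000L) {
  k <- seq.int(q, q + n_direct - 1L)
  tail_from <- q + n_direct
  sum(k^(-a)) + tail_from^(1 - a) / (a - 1) + 0.5 * tail_from^(-a) +
    a * tail_from^(-a - 1) / 12
}

#' Fit a discrete power law to a degree sequence
#'
#' Maximum-likelihood fit of `P(k) ~ k^-alpha` over the tail `k >= xmin`,
#' with `alpha_hat = 1 + n_tail / sum(log(x_i / (xmin - 0.5)))` for each
#' candidate `xmin`, choosing the `xmin` that minimizes the
#' Kolmogorov-Smirnov distance between the tail's empirical CDF and the
#' fitted discrete power law. Zeros are excluded; a reported fit requires at
#' least 10 tail observations.
#'
#' @param degrees non-negative integer degree sequence.
#' @param which label for the fitted sequence (`"in"` or `"out"`).
#' @return list of class `power_law_fit`: `which`, `xmin`, `alpha`,
#'   `ks_distance`, `n_tail`.
#' @export
fit_power_law_mle <- function(degrees, which = c("in", "out")) {
  which <- match.arg(which)
  x <- degrees[degrees > 0]
  if (length(x) == 0) stop("all degrees are zero: nothing to fit")
  if (length(unique(x)) < 2)
    stop("degenerate degree sequence (single distinct value)")
  if (length(x) < 10) stop("need at least 10 positive degrees")
  cands <- sort(unique(x))
  cands <- cands[vapply(cands, function(xm) sum(x >= xm) >= 10, logical(1))]
  cands <- cands[cands < max(x)]
  if (!length(cands)) stop("no xmin candidate leaves a tail of >= 10 values")
  best <- NULL
  for (xm in cands) {
    tail_x <- x[x >= xm]
    n <- length(tail_x)
    alpha <- 1 + n / sum(log(tail_x / (xm - 0.5)))
    if (!is.finite(alpha) || alpha <= 1) next
    # fitted CDF over the observed support
    ks <- seq.int(xm, max(tail_x))
    z <- hurwitz_zeta(alpha, xm)
    cdf_fit <- cumsum(ks^(-alpha)) / z
    ecdf_tail <- cumsum(tabulate(tail_x - xm + 1L, nbins = length(ks))) / n
    ks_dist <- max(abs(ecdf_tail - cdf_fit))
    if (is.null(best) || ks_dist < best$ks_distance)
      best <- list(which = which, xmin = as.integer(xm), alpha = alpha,
                   ks_distance = ks_dist, n_tail = n)
  }
  if (is.null(best)) stop("no admissible power-law fit found")
  class(best) <- "power_law_fit"
  best
}

#' Directed assortativity profile
#'
#' For each degree-pair flavor `(alpha, beta)` in `{in, out}^2`, the Pearson
#' correlation -- taken over directed edges -- between the source node's
#' alpha-degree and the target node's beta-degree (total degrees at the edge
#' endpoints). A coefficient is `NA` when either marginal variance is zero.
#'
#' @param net a `reg_network` or directed igraph.
#' @return named list `r_in_in`, `r_in_out`, `r_out_in`, `r_out_out`.
#' @export
assortativity_profile <- function(net) {
  g <- as_graph(net)
  if (igraph::ecount(g) < 2) stop("need at least two edges")
  el <- igraph::as_edgelist(g, names = FALSE)
  din <- igraph::degree(g, mode = "in")
  dout <- igraph::degree(g, mode = "out")
  cor_or_na <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  list(r_in_in = cor_or_na(din[el[, 1]], din[el[, 2]]),
       r_in_out = cor_or_na(din[el[, 1]], dout[el[, 2]]),
       r_out_in = cor_or_na(dout[el[, 1]], din[el[, 2]]),
       r_out_out = cor_or_na(dout[el[, 1]], dout[el[, 2]]))
}

#' Global transitivity (clustering coefficient)
#'
#' `3 x closed triplets / connected triplets` on the undirected simple
#' projection of the graph; 0 by convention when there is no connected
#' triplet.
#'
#' @param net a `reg_network` or igraph.
#' @return numeric in `[0, 1]`.
#' @export
transitivity_global <- function(net) {
  g <- undirected_projection(as_graph(net))
  t <- igraph::transitivity(g, type = "global")
  if (is.nan(t)) 0 else t
}

#' Path-based metrics on the undirected projection
#'
#' Average shortest path length over all reachable ordered pairs (infinite
#' distances excluded), the diameter (largest finite shortest-path length)
#' and the mean number of distinct neighbors per node.
#'
#' @param net a `reg_network` or igraph.
#' @return list `char_path_length`, `diameter`, `avg_neighbors`.
#' @export
path_metrics <- function(net) {
  g <- undirected_projection(as_graph(net))
  if (igraph::vcount(g) == 0) stop("empty graph")
  if (igraph::ecount(g) == 0)
    stop("no edges: average shortest path length undefined")
  d <- igraph::distances(g)
  finite <- d[is.finite(d) & d > 0]
  list(char_path_length = mean(finite),
       diameter = as.integer(max(finite)),
       avg_neighbors = mean(igraph::degree(g)))
}

#' Small-world-ness against Erdos-Renyi baselines
#'
#' Compares the undirected simple projection's transitivity `T_Net` and
#' average shortest path length `ASL_Net` against the means `T_Rand`,
#' `ASL_Rand` over `n_reps` Erdos-Renyi G(n, m) graphs of the same order and
#' size. Small-world-ness is `S = (T_Net / T_Rand) / (ASL_Net / ASL_Rand)`;
#' `S > 1` flags a small-world topology.
#'
#' @param net a `reg_network` or igraph.
#' @param n_reps number of random replicates (default 100).
#' @param seed RNG seed.
#' @return list of class `small_world_result`: `t_net`, `asl_net`, `t_rand`,
#'   `asl_rand`, `n_reps`, `s`.
#' @export
small_world_ness <- function(net, n_reps = 100L, seed = 1L) {
  g <- undirected_projection(as_graph(net))
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  t_net <- transitivity_global(g)
  asl_net <- path_metrics(g)$char_path_length
  set.seed(seed)
  ts <- asls <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    er <- igraph::sample_gnm(n, m)
    tt <- igraph::transitivity(er, type = "global")
    ts[i] <- if (is.nan(tt)) 0 else tt
    asls[i] <- igraph::mean_distance(er)
  }
  t_rand <- mean(ts)
  asl_rand <- mean(asls)
  s <- if (t_rand > 0 && t_net > 0)
    (t_net / t_rand) / (asl_net / asl_rand) else NA_real_
  structure(list(t_net = t_net, asl_net = asl_net, t_rand = t_rand,
                 asl_rand = asl_rand, n_reps = n_reps, s = s),
            class = "small_world_result")
}

#' Compute small-world-ness from its four components
#'
#' `S = (T_Net / T_Rand) / (ASL_Net / ASL_Rand)`; useful for recomputing a
#' verdict from a published table of components.
#'
#' @param t_net,t_rand,asl_net,asl_rand the four components (all `> 0`).
#' @return numeric small-world-ness.
#' @export
small_worldness_from_components <- function(t_net, t_rand, asl_net,
                                            asl_rand) {
  if (any(c(t_net, t_rand, asl_net, asl_rand) <= 0))
    stop("all components must be > 0 for a defined S")
  (t_net / t_rand) / (asl_net / asl_rand)
}

#' Strongly connected components
#'
#' @param net a `reg_network` or directed igraph.
#' @return list with `components` (list of node-name vectors sorted by
#'   decreasing size) and `largest` (size of the largest SCC).
#' @export
strongly_connected_components <- function(net) {
  g <- as_graph(net)
  comp <- igraph::components(g, mode = "strong")
  nm <- if (!is.null(igraph::V(g)$name)) igraph::V(g)$name
        else as.character(seq_len(igraph::vcount(g)))
  parts <- split(nm, comp$membership)
  parts <- parts[order(-vapply(parts, length, integer(1)))]
  names(parts) <- NULL
  list(components = parts,
       largest = if (length(parts)) length(parts[[1]]) else 0L)
}

#' Node centralities and top-k ranking
#'
#' In-degree, out-degree, directed betweenness (shortest-path pair
#' dependencies) and a disconnected-safe closeness,
#' `(r / (n - 1)) * (r / sum of distances to the r reachable nodes)`,
#' computed on outgoing directed paths. Ranking ties are broken by node id.
#'
#' @param net a `reg_network` or directed igraph.
#' @param top_k how many nodes to report per ranking (default 10).
#' @return list with `table` (per-node data.frame: `id`, `in_degree`,
#'   `out_degree`, `closeness`, `betweenness`) and `top` (named list of
#'   top-k id vectors per measure).
#' @export
centrality_table <- function(net, top_k = 10L) {
  g <- as_graph(net)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  ids <- if (!is.null(igraph::V(g)$name)) igraph::V(g)$name
         else as.character(seq_len(n))
  din <- igraph::degree(g, mode = "in")
  dout <- igraph::degree(g, mode = "out")
  btw <- igraph::betweenness(g, directed = TRUE)
  d <- igraph::distances(g, mode = "out")
  clo <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    reach <- dv[is.finite(dv)]
    r <- length(reach)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
  tab <- data.frame(id = ids, in_degree = unname(din),
                    out_degree = unname(dout), closeness = clo,
                    betweenness = unname(btw), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  rank_top <- function(x) {
    ord <- order(-x, tab$id)
    tab$id[ord][seq_len(min(top_k, n))]
  }
  list(table = tab,
       top = list(in_degree = rank_top(tab$in_degree),
                  out_degree = rank_top(tab$out_degree),
                  closeness = rank_top(tab$closeness),
                  betweenness = rank_top(tab$betweenness)))
}

#' Full topology report for a regulatory network
#'
#' Bundles node/edge counts, the largest strongly connected component,
#' diameter, characteristic path length, average neighbor count, the
#' directed assortativity profile, in- and out-degree power-law fits and
#' small-world-ness into one structure shaped like the published
#' per-stress topology tables.
#'
#' @param net a `reg_network` or directed igraph.
#' @param er_reps Erdos-Renyi replicates for small-world-ness.
#' @param seed RNG seed for the baseline graphs.
#' @param fit_degree_tail fit power laws to the degree tails (needs >= 10
#'   positive degrees; skipped with `NA` fields otherwise unless forced).
#' @param top_k centrality ranking depth.
#' @return list of class `topology_report`.
#' @export
topology_report <- function(net, er_reps = 100L, seed = 1L,
                            fit_degree_tail = TRUE, top_k = 10L) {
  g <- as_graph(net)
  scc <- strongly_connected_components(g)
  pm <- path_metrics(g)
  fits <- list(in_degree = NULL, out_degree = NULL)
  if (fit_degree_tail) {
    fits$in_degree <- tryCatch(
      fit_power_law_mle(igraph::degree(g, mode = "in"), "in"),
      error = function(e) NULL)
    fits$out_degree <- tryCatch(
      fit_power_law_mle(igraph::degree(g, mode = "out"), "out"),
      error = function(e) NULL)
  }
  structure(list(
    n_nodes = as.integer(igraph::vcount(g)),
    n_edges = as.integer(igraph::ecount(g)),
    largest_scc = scc$largest,
    diameter = pm$diameter,
    char_path_length = pm$char_path_length,
    avg_neighbors = pm$avg_neighbors,
    assortativity = assortativity_profile(g),
    power_law = fits,
    small_world = small_world_ness(g, n_reps = er_reps, seed = seed),
    centrality = centrality_table(g, top_k = top_k),
    stress_label = if (inherits(net, "reg_network")) net$stress_label
                   else NA_character_
  ), class = "topology_report")
}

#' Write a topology report to JSON and a table-shaped TSV
#'
#' @param report a `topology_report`.
#' @param json_path,tsv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_topology_report <- function(report, json_path = NULL,
                                  tsv_path = NULL) {
  stopifnot(inherits(report, "topology_report"))
  flat <- list(
    n_nodes = report$n_nodes, n_edges = report$n_edges,
    largest_scc = report$largest_scc, diameter = report$diameter,
    char_path_length = report$char_path_length,
    avg_neighbors = report$avg_neighbors,
    assortativity = report$assortativity,
    power_law = lapply(report$power_law, function(f)
      if (is.null(f)) NULL else unclass(f)),
    small_world = unclass(report$small_world),
    stress_label = report$stress_label)
  if (!is.null(json_path))
    jsonlite::write_json(flat, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(tsv_path)) {
    rows <- data.frame(
      attribute = c("Number of edges", "Number of nodes",
                    "Largest SCC size", "Graph diameter",
                    "Characteristic path length",
                    "The average number of neighbors",
                    "Assortativity (in-in)", "Assortativity (in-out)",
                    "Assortativity (out-in)", "Assortativity (out-out)",
                    "Small-world-ness"),
      value = c(report$n_edges, report$n_nodes, report$largest_scc,
                report$diameter, report$char_path_length,
                report$avg_neighbors, report$assortativity$r_in_in,
                report$assortativity$r_in_out,
                report$assortativity$r_out_in,
                report$assortativity$r_out_out, report$small_world$s),
      stringsAsFactors = FALSE)
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Topology report",
      if (!is.na(x$stress_label)) paste0("(", x$stress_label, ")"), "\n")
  cat(sprintf("  nodes %d, edges %d, largest SCC %d\n",
              x$n_nodes, x$n_edges, x$largest_scc))
  cat(sprintf("  diameter %d, characteristic path length %.3f, avg neighbors %.3f\n",
              x$diameter, x$char_path_length, x$avg_neighbors))
  a <- x$assortativity
  cat(sprintf("  assortativity in-in %.3f, in-out %.3f, out-in %.3f, out-out %.3f\n",
              a$r_in_in, a$r_in_out, a$r_out_in, a$r_out_out))
  sw <- x$small_world
  cat(sprintf("  small-world-ness S = %.3f (T %.4f vs %.4f; ASL %.3f vs %.3f)\n",
              sw$s, sw$t_net, sw$t_rand, sw$asl_net, sw$asl_rand))
  invisible(x)
}
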