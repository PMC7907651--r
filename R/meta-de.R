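#' Per-study effect ranks for rank-product meta-analysis
#'
#' For each study the per-gene contrast is `mean(case) - mean(control)` log2
#' fold change; genes are then ranked within each study so rank 1 is the
#' most extreme in the requested direction (largest log2FC for `"up"`,
#' smallest for `"down"`), with average ranks for ties. The gene universe is
#' the intersection across studies; genes dropped by the intersection are
#' recorded in the result.
#'
#' @param studies list of [expression_study()] objects.
#' @param direction `"up"` or `"down"`.
#' @return list of class `rank_matrix`: `ranks` (genes x contrasts matrix),
#'   `log2fc` (same shape), `direction`, `K` (number of contrasts),
#'   `dropped` (gene ids lost to the intersection).
#' @export
compute_rank_matrix <- function(studies, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(studies) < 1) stop("need at least one study")
  if (length(studies) < 2)
    warning("only one study: meta-analysis degenerates to a single ranking")
  universes <- lapply(studies, function(s) rownames(s$matrix))
  genes <- Reduce(intersect, universes)
  if (length(genes) == 0) stop("studies have disjoint gene sets")
  dropped <- setdiff(unique(unlist(universes)), genes)

  lfc <- vapply(studies, function(s) {
    m <- s$matrix[genes, , drop = FALSE]
    rowMeans(m[, s$group == "case", drop = FALSE]) -
      rowMeans(m[, s$group == "control", drop = FALSE])
  }, numeric(length(genes)))
  lfc <- matrix(lfc, nrow = length(genes),
                dimnames = list(genes, vapply(studies, `[[`, "",
                                              "study_id")))
  ranks <- apply(lfc, 2, function(x) {
    if (direction == "up") rank(-x, ties.method = "average")
    else rank(x, ties.method = "average")
  })
  structure(list(ranks = ranks, log2fc = lfc, direction = direction,
                 K = ncol(ranks), dropped = dropped),
            class = "rank_matrix")
}

#' Rank product statistic
#'
#' The rank product of a gene is the geometric mean of its ranks across the
#' `K` contrasts, `RP_g = (prod_i r_gi)^(1/K)`; smaller values mean the gene
#' is consistently extreme across studies.
#'
#' @param rm a `rank_matrix` from [compute_rank_matrix()].
#' @return named numeric vector of per-gene rank products.
#' @export
rank_product <- function(rm) {
  stopifnot(inherits(rm, "rank_matrix"))
  exp(rowMeans(log(rm$ranks)))
}

#' Permutation-estimated percentage of false positives (PFP)
#'
#' For each of `n_perm` permutations every contrast's rank column is
#' shuffled independently and the rank products recomputed. The expected
#' number of false positives at a gene's RP is
#' `E(g) = #\{permuted RP <= RP_g\} / n_perm`, and the raw PFP is `E(g)`
#' divided by the gene's position in the observed RP ordering. The raw
#' estimate is then monotonized with a running maximum in increasing-RP
#' order (a step-up envelope, as for q-values) and reported uncapped, so
#' values above 1 are possible.
#'
#' @param rm a `rank_matrix`.
#' @param rp rank products from [rank_product()].
#' @param n_perm number of permutations (`>= 1`).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return named numeric vector of per-gene PFP estimates.
#' @export
permutation_pfp <- function(rm, rp, n_perm = 1000L, seed) {
  stopifnot(inherits(rm, "rank_matrix"), n_perm >= 1)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- length(rp)
  counts <- numeric(n)
  for (b in seq_len(n_perm)) {
    perm <- apply(rm$ranks, 2, sample)
    rpb <- sort(exp(rowMeans(log(perm))))
    counts <- counts + findInterval(rp, rpb)
  }
  e <- counts / n_perm
  pos <- rank(rp, ties.method = "max")
  pfp <- e / pos
  ord <- order(rp)
  pfp[ord] <- cummax(pfp[ord])
  # tied rank products receive a common (maximal) estimate
  pfp <- stats::ave(pfp, rp, FUN = max)
  names(pfp) <- names(rp)
  pfp
}

#' Call differentially expressed genes at a PFP threshold
#'
#' Genes with `pfp < threshold` in either direction are called; a gene
#' significant in both directions is internally inconsistent and is rejected
#' with a warning.
#'
#' @param up,down data.frames with columns `gene_id`, `rp`, `pfp` (one per
#'   direction), e.g. assembled from [rank_product()] and
#'   [permutation_pfp()].
#' @param threshold PFP call threshold (default 0.01).
#' @return data.frame of calls: `gene_id`, `direction`, `rp`, `pfp`.
#' @export
call_degs <- function(up, down, threshold = 0.01) {
  pick <- function(tab, dir) {
    sel <- tab[tab$pfp < threshold, , drop = FALSE]
    if (nrow(sel)) sel$direction <- dir
    sel
  }
  u <- pick(up, "up")
  d <- pick(down, "down")
  both <- intersect(u$gene_id, d$gene_id)
  if (length(both)) {
    warning("gene(s) significant in both directions rejected: ",
            paste(both, collapse = ", "))
    u <- u[!u$gene_id %in% both, , drop = FALSE]
    d <- d[!d$gene_id %in% both, , drop = FALSE]
  }
  out <- rbind(u, d)
  if (nrow(out) == 0)
    return(data.frame(gene_id = character(), direction = character(),
                      rp = numeric(), pfp = numeric(),
                      stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[, c("gene_id", "direction", "rp", "pfp")]
}

#' Run the full rank-product meta-analysis on a set of studies
#'
#' Convenience driver: computes both direction-specific rank matrices, rank
#' products and permutation PFPs, and calls DEGs at the threshold.
#'
#' @inheritParams compute_rank_matrix
#' @inheritParams permutation_pfp
#' @inheritParams call_degs
#' @return list with `calls` (data.frame as [call_degs()]), and per-direction
#'   tables `up` and `down` (`gene_id`, `rp`, `pfp`).
#' @export
meta_de <- function(studies, n_perm = 1000L, seed, threshold = 0.01) {
  tabs <- lapply(c(up = "up", down = "down"), function(dir) {
    rm <- compute_rank_matrix(studies, dir)
    rp <- rank_product(rm)
    pfp <- permutation_pfp(rm, rp, n_perm = n_perm, seed = seed)
    data.frame(gene_id = names(rp), rp = unname(rp), pfp = unname(pfp),
               stringsAsFactors = FALSE)
  })
  list(calls = call_degs(tabs$up, tabs$down, threshold),
       up = tabs$up, down = tabs$down)
}

#' Compare DEG signatures across stresses
#'
#' Computes Venn-style exclusive subset counts over two or more per-stress
#' call lists, plus -- for the all-stress intersection -- the number of genes
#' with an identical direction everywhere (the conserved-response count).
#'
#' @param calls named list (one element per stress) of data.frames with
#'   columns `gene_id` and `direction`.
#' @return list with `subset_counts` (named integer vector keyed by
#'   `"A+B"`-style stress combinations, exclusive membership),
#'   `common_all` (genes present under every stress) and `conserved_all`
#'   (subset of those with the same direction under every stress).
#' @export
compare_stress_signatures <- function(calls) {
  if (length(calls) < 2) stop("need at least two stresses")
  stresses <- names(calls)
  if (is.null(stresses) || any(stresses == ""))
    stop("calls must be a fully named list")
  membership <- lapply(calls, function(x) unique(x$gene_id))
  universe <- unique(unlist(membership))
  key <- vapply(universe, function(g) {
    paste(stresses[vapply(membership, function(s) g %in% s, logical(1))],
          collapse = "+")
  }, character(1))
  subset_counts <- table(key)
  all_key <- paste(stresses, collapse = "+")
  common <- universe[key == all_key]
  dirs <- vapply(common, function(g) {
    d <- vapply(calls, function(x) x$direction[match(g, x$gene_id)],
                character(1))
    length(unique(d)) == 1L
  }, logical(1))
  list(subset_counts = c(subset_counts),
       common_all = length(common),
       conserved_all = sum(dirs))
}
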