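make_study <- function(id, lfc, r = 2, noise = 0) {
  genes <- paste0("g", seq_along(lfc))
  m <- matrix(0, length(lfc), 2 * r,
              dimnames = list(genes, paste0("s", 1:(2 * r))))
  group <- c(rep("control", r), rep("case", r))
  m[, group == "case"] <- m[, group == "case"] + lfc
  if (noise > 0) m <- m + rnorm(length(m), sd = noise)
  expression_study(id, m, group)
}

test_that("effect ranking follows direction and average-rank ties", {
  s <- make_study("a", c(2, 0, -1))
  expect_warning(up <- compute_rank_matrix(list(s), "up"), "single")
  expect_equal(unname(up$ranks[, 1]), c(1, 2, 3))
  down <- suppressWarnings(compute_rank_matrix(list(s), "down"))
  expect_equal(unname(down$ranks[, 1]), c(3, 2, 1))
  tied <- suppressWarnings(
    compute_rank_matrix(list(make_study("t", c(1, 1, 0))), "up"))
  expect_equal(unname(tied$ranks[, 1]), c(1.5, 1.5, 3))
  expect_error(compute_rank_matrix(list(), "up"), "at least one")
})

test_that("rank product is the geometric mean and permutation-invariant", {
  rm <- structure(list(ranks = rbind(g1 = c(1, 1), g2 = c(2, 3),
                                     g3 = c(3, 2)),
                       direction = "up", K = 2),
                  class = "rank_matrix")
  rp <- rank_product(rm)
  expect_equal(unname(rp["g1"]), 1)
  expect_equal(unname(rp["g2"]), sqrt(6))
  expect_equal(unname(rp["g2"]), unname(rp["g3"]))
})

test_that("rank product ignores monotone transforms of the effects", {
  set.seed(42)
  lfc <- rnorm(30)
  s1 <- make_study("a", lfc)
  s2 <- make_study("b", 2 * lfc + 1)     # strictly monotone transform
  rp1 <- rank_product(compute_rank_matrix(list(s1, s1), "up"))
  rp2 <- rank_product(compute_rank_matrix(list(s2, s2), "up"))
  expect_equal(rp1, rp2)
})

test_that("permutation PFP matches a brute-force single permutation", {
  set.seed(8)
  s <- list(make_study("a", rnorm(20), noise = 0.1),
            make_study("b", rnorm(20), noise = 0.1))
  rm <- compute_rank_matrix(s, "up")
  rp <- rank_product(rm)
  pfp <- permutation_pfp(rm, rp, n_perm = 1, seed = 99)
  # replay the identical single permutation draw and count by hand
  set.seed(99)
  perm <- apply(rm$ranks, 2, sample)
  rpb <- exp(rowMeans(log(perm)))
  e <- vapply(rp, function(x) sum(rpb <= x), numeric(1))
  raw <- e / rank(rp, ties.method = "max")
  ord <- order(rp)
  raw[ord] <- cummax(raw[ord])
  expect_equal(unname(pfp), unname(raw))
})

test_that("PFP is monotone in RP order and 0 for untouchable genes", {
  set.seed(10)
  s <- lapply(1:3, function(i)
    make_study(paste0("s", i), c(rep(5, 3), rnorm(197)), noise = 0.2))
  rm <- compute_rank_matrix(s, "up")
  rp <- rank_product(rm)
  pfp <- permutation_pfp(rm, rp, n_perm = 100, seed = 3)
  ord <- order(rp)
  expect_true(all(diff(pfp[ord]) >= -1e-12))
  expect_equal(unname(pfp[which.min(rp)]), 0)
})

test_that("DEG calling applies the threshold and rejects two-direction hits", {
  up <- data.frame(gene_id = c("g1", "g2"), rp = c(1, 5),
                   pfp = c(0.005, 0.02))
  down <- data.frame(gene_id = c("g2", "g3"), rp = c(2, 9),
                     pfp = c(0.5, 0.8))
  calls <- call_degs(up, down, threshold = 0.01)
  expect_identical(calls$gene_id, "g1")
  expect_identical(nrow(call_degs(up, down, threshold = 0)), 0L)
  both <- data.frame(gene_id = "g1", rp = 1, pfp = 0.001)
  expect_warning(res <- call_degs(both, both), "both directions")
  expect_identical(nrow(res), 0L)
})

test_that("planted DEGs are recovered in a well-powered scenario", {
  cfg <- scenario_config(seed = 2, n_genes = 2000, frac_de = 0.05,
                         effect_size = 2, n_studies = 3)
  sim <- simulate_expression_studies(cfg)
  res <- meta_de(sim$studies, n_perm = 200, seed = 2, threshold = 0.01)
  recall <- mean(sim$truth$gene_id %in% res$calls$gene_id)
  expect_gte(recall, 0.8)
  hit <- merge(res$calls, sim$truth, by = "gene_id")
  expect_true(all(hit$direction.x == hit$direction.y))
})

test_that("stress-signature comparison matches set algebra", {
  a <- data.frame(gene_id = "g1", direction = "up")
  b <- data.frame(gene_id = "g1", direction = "up")
  cmp <- compare_stress_signatures(list(A = a, B = b))
  expect_identical(cmp$common_all, 1L)
  expect_identical(cmp$conserved_all, 1L)
  b2 <- data.frame(gene_id = "g1", direction = "down")
  cmp2 <- compare_stress_signatures(list(A = a, B = b2))
  expect_identical(cmp2$common_all, 1L)
  expect_identical(cmp2$conserved_all, 0L)

  set.seed(5)
  universe <- paste0("g", 1:300)
  sets <- lapply(1:3, function(i)
    data.frame(gene_id = sample(universe, 100),
               direction = sample(c("up", "down"), 100, replace = TRUE)))
  names(sets) <- c("cold", "drought", "salt")
  cmp3 <- compare_stress_signatures(sets)
  # brute-force enumeration over the union
  union_genes <- unique(unlist(lapply(sets, `[[`, "gene_id")))
  expect_identical(sum(cmp3$subset_counts), length(union_genes))
  key <- vapply(union_genes, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s$gene_id,
                             logical(1))], collapse = "+"), character(1))
  expect_identical(unname(cmp3$subset_counts[names(table(key))]),
                   unname(as.integer(table(key))))
  common <- union_genes[key == "cold+drought+salt"]
  expect_identical(cmp3$common_all, length(common))
})
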