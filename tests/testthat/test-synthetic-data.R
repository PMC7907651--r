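test_that("scenario configuration validates its fields", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(n_genes = 0), "count")
  expect_error(scenario_config(frac_de = 1.2), "frac_de")
  expect_error(scenario_config(library_size = 10, n_mirnas = 50),
               "library_size")
  expect_error(scenario_config(transcript_len = 10), "transcript_len")
})

test_that("expression simulation is deterministic and honors the null", {
  cfg <- scenario_config(seed = 1, n_genes = 100, noise_sd = 1)
  a <- simulate_expression_studies(cfg)
  b <- simulate_expression_studies(cfg)
  expect_identical(a, b)

  null_cfg <- scenario_config(seed = 3, n_genes = 100, frac_de = 0,
                              noise_sd = 1)
  nl <- simulate_expression_studies(null_cfg)
  expect_identical(nrow(nl$truth), 0L)
})

test_that("planted effect sizes average to the configured log2FC", {
  cfg <- scenario_config(seed = 5, n_genes = 1000, frac_de = 0.05,
                         effect_size = 2, n_studies = 3)
  sim <- simulate_expression_studies(cfg)
  up <- sim$truth$gene_id[sim$truth$direction == "up"]
  lfc <- rowMeans(vapply(sim$studies, function(s) {
    rowMeans(s$matrix[up, s$group == "case", drop = FALSE]) -
      rowMeans(s$matrix[up, s$group == "control", drop = FALSE])
  }, numeric(length(up))))
  # mean over planted up-genes: SE = noise_sd * sqrt(2/r) / sqrt(n_up * K)
  se <- cfg$noise_sd * sqrt(2 / cfg$n_replicates) /
    sqrt(length(up) * cfg$n_studies)
  expect_lt(abs(mean(lfc) - 2), 3 * se)
})

test_that("sRNA libraries realize the AGO1 detectability plan", {
  cfg <- scenario_config(seed = 7, n_mirnas = 100)
  sim <- simulate_srna_libraries(cfg)
  ago1 <- Filter(function(l) l$kind == "ago1", sim$libraries)
  rpm <- vapply(ago1, rpm_normalize, numeric(cfg$n_mirnas))
  det <- sim$truth$ago1_detectable
  expect_true(all(apply(rpm[det, , drop = FALSE] >= 3, 1, any)))
  others <- setdiff(paste0("m", 1:100), det)
  expect_true(all(rpm[others, ] < 3))
  expect_identical(sim, simulate_srna_libraries(cfg))
})

test_that("zero dispersion gives Poisson-like counts", {
  cfg <- scenario_config(seed = 9, n_mirnas = 2000, nb_dispersion = 0,
                         library_size = 2e6, frac_de = 0)
  sim <- simulate_srna_libraries(cfg)
  ctrl <- Filter(function(l) l$kind == "control", sim$libraries)
  cnt <- vapply(ctrl, `[[`, numeric(cfg$n_mirnas), "counts")
  # variance/mean ratio across replicate draws of the same mean is ~1
  ratio <- apply(cnt, 1, var) / pmax(rowMeans(cnt), 1)
  expect_lt(abs(median(ratio[rowMeans(cnt) > 50]) - 1), 0.35)
})

test_that("planted sites score as designed and null plans stay empty", {
  cfg <- scenario_config(
    seed = 11, n_transcripts = 5, transcript_len = 300,
    site_plan = list(list(),                      # perfect complement
                     list(gu_pos = 5),            # one wobble in the seed
                     list(mismatch_pos = 1)))     # one mismatch outside it
  sim <- simulate_transcripts_and_sites(cfg)
  expect_identical(sim$truth$expectation, c(0, 1, 1))
  # scanning recovers each planted site at its recorded coordinate
  hits <- predict_targets(sim$mirnas[1], sim$transcripts, cutoff = 0)
  expect_identical(hits$start, sim$truth$start[1])
  expect_identical(hits$cleavage_pos, sim$truth$cleavage_pos[1])

  null_sim <- simulate_transcripts_and_sites(
    scenario_config(seed = 13, n_transcripts = 5, transcript_len = 300))
  expect_identical(nrow(null_sim$truth), 0L)
  expect_identical(
    nrow(predict_targets(null_sim$mirnas, null_sim$transcripts,
                         cutoff = 0)), 0L)
})

test_that("degradome simulation realizes each planted category", {
  plan <- lapply(c(0, 1, 2, 3, 4, NA), function(k) list(category = k))
  cfg <- scenario_config(seed = 15, n_transcripts = 6, transcript_len = 300,
                         site_plan = plan)
  sim <- simulate_transcripts_and_sites(cfg)
  deg <- simulate_degradome(sim$transcripts, sim$truth, cfg)
  got <- mapply(function(tx, pos) {
    prof <- deg$library$profiles[[tx]]
    classify_cleavage_site(if (is.null(prof)) numeric(0) else prof, pos)
  }, sim$truth$transcript_id, sim$truth$cleavage_pos)
  expect_equal(unname(got), sim$truth$category)
  # category 4 means exactly one raw tag at the cleavage position
  i4 <- which(sim$truth$category == 4)
  prof <- deg$library$profiles[[sim$truth$transcript_id[i4]]]
  expect_identical(unname(prof[as.character(sim$truth$cleavage_pos[i4])]), 1)
})

test_that("regulon tables match the configured density and determinism", {
  cfg0 <- scenario_config(seed = 17, regulon_density = 0)
  expect_identical(nrow(simulate_regulon_tables(cfg0)$regulon), 0L)

  cfg <- scenario_config(seed = 19, n_tfs = 10, regulon_density = 5,
                         n_genes = 500, n_mirnas = 50)
  tab <- simulate_regulon_tables(cfg)$regulon
  mean_deg <- nrow(tab) / cfg$n_tfs
  se <- sqrt(5 / cfg$n_tfs)  # binomial out-degree, variance ~ density
  expect_lt(abs(mean_deg - 5), 3 * se)
  expect_identical(simulate_regulon_tables(cfg)$regulon, tab)
  mim <- simulate_regulon_tables(cfg, de_mirnas = "m1")$mimics
  expect_true("m1" %in% mim$mirna_id)
})

test_that("reference graph families have the promised structure", {
  er <- generate_reference_graph("erdos_renyi", n = 100, m_or_p = 400,
                                 seed = 7)
  expect_identical(igraph::ecount(er), 400)
  expect_false(igraph::any_loop(er))
  expect_false(igraph::any_multiple(er))
  expect_error(generate_reference_graph("erdos_renyi", n = 5, m_or_p = 100),
               "infeasible")

  ring <- generate_reference_graph("ring_lattice", n = 20, k = 4)
  und <- igraph::as_undirected(ring, mode = "collapse")
  expect_true(all(igraph::degree(und) == 4))
  expect_equal(igraph::transitivity(und, type = "global"), 0.5)

  sf <- generate_reference_graph("scale_free", n = 5000, m_or_p = 3,
                                 seed = 21)
  fit <- fit_power_law_mle(igraph::degree(sf, mode = "in"), "in")
  expect_gt(fit$alpha, 2)
  expect_lt(fit$alpha, 3.5)
})
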