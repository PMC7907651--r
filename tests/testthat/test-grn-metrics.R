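digraph <- function(...) igraph::graph_from_literal(..., simplify = FALSE)

test_that("SCC, transitivity and path metrics agree on hand examples", {
  g <- igraph::make_graph(c("a", "b", "b", "a", "b", "c"), directed = TRUE)
  scc <- strongly_connected_components(g)
  expect_identical(scc$largest, 2L)
  expect_setequal(scc$components[[1]], c("a", "b"))

  dag <- igraph::make_graph(c("a", "b", "a", "c", "b", "d"), directed = TRUE)
  expect_identical(strongly_connected_components(dag)$largest, 1L)

  tri <- igraph::make_graph(c(1, 2, 2, 3, 3, 1), directed = TRUE)
  expect_equal(transitivity_global(tri), 1)
  star <- igraph::make_star(6, mode = "out")
  expect_equal(transitivity_global(star), 0)

  path <- igraph::make_graph(c("a", "b", "b", "c"), directed = TRUE)
  pm <- path_metrics(path)
  expect_equal(pm$char_path_length, 4 / 3)
  expect_identical(pm$diameter, 2L)

  two <- igraph::make_graph(c(1, 2, 3, 4), directed = TRUE)
  pm2 <- path_metrics(two)
  expect_equal(pm2$char_path_length, 1)
  expect_identical(pm2$diameter, 1L)
})

test_that("centralities match hand-computed values", {
  path <- igraph::make_graph(c("a", "b", "b", "c"), directed = TRUE)
  ct <- centrality_table(path)
  expect_equal(ct$table$betweenness[ct$table$id == "b"], 1)
  expect_equal(sum(ct$table$betweenness), 1)

  star <- igraph::make_graph(c(rbind("hub", paste0("l", 1:5))),
                             directed = TRUE)
  ct2 <- centrality_table(star)
  expect_equal(ct2$table$closeness[ct2$table$id == "hub"], 1)
  expect_true(all(ct2$table$closeness[ct2$table$id != "hub"] == 0))
})

test_that("directed metrics equal brute-force oracles on random graphs", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(8:30, 1)
    adj <- random_digraph_adj(n, p = runif(1, 0.08, 0.3))
    if (sum(adj) < 2) next
    g <- adj_to_igraph(adj)

    # SCC partition
    sizes <- sort(vapply(strongly_connected_components(g)$components,
                         length, integer(1)), decreasing = TRUE)
    expect_identical(sizes, bf_scc_sizes(adj))

    # betweenness
    expect_equal(unname(igraph::betweenness(g, directed = TRUE)),
                 bf_betweenness(adj), tolerance = 1e-10)

    # assortativity profile
    got <- assortativity_profile(g)
    want <- bf_assortativity_profile(adj)
    for (k in names(want)) expect_equal(got[[k]], want[[k]],
                                        tolerance = 1e-12)

    # undirected projection: transitivity and path metrics
    und <- pmax(adj, t(adj))
    expect_equal(transitivity_global(g), bf_transitivity(und),
                 tolerance = 1e-12)
    pm <- path_metrics(g)
    oracle <- bf_asl_diameter(und)
    expect_equal(pm$char_path_length, oracle$asl, tolerance = 1e-12)
    expect_identical(pm$diameter, as.integer(oracle$diameter))
  }
})

test_that("degenerate assortativity is reported as undefined", {
  cyc <- igraph::make_ring(4, directed = TRUE)
  prof <- assortativity_profile(cyc)
  expect_true(all(is.na(unlist(prof))))
  expect_error(assortativity_profile(igraph::make_graph(c(1, 2),
                                                        directed = TRUE)),
               "two edges")
})

test_that("a two-edge graph with varying endpoint degrees correlates to ±1", {
  g <- igraph::make_graph(c("a", "b", "c", "b"), directed = TRUE)
  prof <- assortativity_profile(g)
  # both edges share identical endpoint degrees -> zero variance
  expect_true(is.na(prof$r_in_in))
  g2 <- igraph::make_graph(c("a", "b", "c", "a"), directed = TRUE)
  el <- igraph::as_edgelist(g2, names = FALSE)
  din <- igraph::degree(g2, mode = "in")
  dout <- igraph::degree(g2, mode = "out")
  expect_equal(assortativity_profile(g2)$r_in_out,
               bf_edge_pearson(din[el[, 1]], dout[el[, 2]]))
  expect_equal(abs(assortativity_profile(g2)$r_in_out), 1)
})

test_that("power-law fitting recovers alpha and rejects degenerate input", {
  set.seed(31)
  x <- rpowerlaw(5000, alpha = 2.5, xmin = 1)
  fit <- fit_power_law_mle(x, "in")
  expect_gt(fit$alpha, 2.3)
  expect_lt(fit$alpha, 2.7)
  expect_gte(fit$n_tail, 10)
  expect_true(fit$ks_distance >= 0 && fit$ks_distance <= 1)

  # independent cross-check against igraph's Clauset-style fitter
  ifit <- igraph::fit_power_law(x, implementation = "plfit")
  expect_lt(abs(fit$alpha - ifit$alpha), 0.15)

  # a geometric sample fits visibly worse than a power-law sample
  set.seed(32)
  geo <- stats::rgeom(5000, prob = 0.4) + 1
  gfit <- fit_power_law_mle(geo, "in")
  expect_gt(gfit$ks_distance, fit$ks_distance)

  expect_error(fit_power_law_mle(rep(0, 20)), "zero")
  expect_error(fit_power_law_mle(rep(5, 50)), "degenerate")
})

test_that("small-world-ness is computed from its components", {
  expect_equal(small_worldness_from_components(0.042, 0.012, 3.329, 3.011),
               (0.042 / 0.012) / (3.329 / 3.011))
  expect_error(small_worldness_from_components(0, 0.01, 2, 2), "> 0")

  g <- generate_reference_graph("rewired_lattice", n = 300, k = 10,
                                p_rewire = 0.05, seed = 5)
  sw <- small_world_ness(g, n_reps = 15, seed = 5)
  expect_gt(sw$s, 1)
  expect_equal(sw$s, (sw$t_net / sw$t_rand) / (sw$asl_net / sw$asl_rand))
})

test_that("degree sums and topology report are self-consistent", {
  g <- generate_reference_graph("erdos_renyi", n = 80, m_or_p = 300,
                                seed = 3)
  expect_identical(sum(igraph::degree(g, mode = "in")),
                   sum(igraph::degree(g, mode = "out")))
  expect_identical(sum(igraph::degree(g, mode = "in")),
                   igraph::ecount(g))
  rep <- topology_report(g, er_reps = 10, seed = 1,
                         fit_degree_tail = FALSE)
  expect_equal(rep$n_nodes, igraph::vcount(g))
  expect_identical(rep$largest_scc,
                   strongly_connected_components(g)$largest)
  expect_equal(rep$char_path_length, path_metrics(g)$char_path_length)
  expect_equal(rep$assortativity, assortativity_profile(g))

  tmp <- tempfile(fileext = ".json")
  write_topology_report(rep, json_path = tmp)
  parsed <- jsonlite::read_json(tmp)
  expect_identical(parsed$n_nodes, rep$n_nodes)
  expect_equal(parsed$small_world$s, rep$small_world$s)
})
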