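#' Pipeline configuration
#'
#' Thresholds, seeds and optional file inputs for [run_pipeline()]. When a
#' file path is supplied for a stage its contents replace the synthetic
#' input for that stage; every supplied path is checked before any stage
#' runs (fail fast).
#'
#' @param scenario a [scenario_config()] describing the synthetic inputs.
#' @param out_dir output directory (created if needed).
#' @param pfp_threshold PFP call threshold for DEGs (default 0.01).
#' @param rpm_threshold AGO1 accumulation threshold in RPM (default 3).
#' @param expectation_cutoff target-site expectation cutoff (default 5).
#' @param de_alpha,de_min_lfc miRNA DE caller parameters.
#' @param n_perm rank-product permutations (default 200).
#' @param er_reps Erdos-Renyi replicates for small-world-ness (default 50).
#' @param mirna_fasta,transcript_fasta,degradome_tsv,regulon_csv optional
#'   file inputs overriding the corresponding synthetic stage.
#' @param run_metrics compute the topology report (default `TRUE`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            out_dir = tempfile("stressgrn_"),
                            pfp_threshold = 0.01, rpm_threshold = 3,
                            expectation_cutoff = 5, de_alpha = 0.05,
                            de_min_lfc = 1, n_perm = 200L, er_reps = 50L,
                            mirna_fasta = NULL, transcript_fasta = NULL,
                            degradome_tsv = NULL, regulon_csv = NULL,
                            run_metrics = TRUE) {
  validate_scenario_config(scenario)
  if (pfp_threshold < 0 || de_alpha <= 0 || de_alpha > 1 ||
      rpm_threshold < 0 || n_perm < 1)
    stop("threshold out of legal range")
  cfg <- list(scenario = scenario, out_dir = out_dir,
              pfp_threshold = pfp_threshold, rpm_threshold = rpm_threshold,
              expectation_cutoff = expectation_cutoff, de_alpha = de_alpha,
              de_min_lfc = de_min_lfc, n_perm = as.integer(n_perm),
              er_reps = as.integer(er_reps), mirna_fasta = mirna_fasta,
              transcript_fasta = transcript_fasta,
              degradome_tsv = degradome_tsv, regulon_csv = regulon_csv,
              run_metrics = isTRUE(run_metrics))
  for (f in c("mirna_fasta", "transcript_fasta", "degradome_tsv",
              "regulon_csv")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("pipeline input '", f, "' does not exist: ", p)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                              auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end regulatory-network pipeline
#'
#' Executes the stages in dependency order on seeded synthetic inputs (or
#' supplied files): expression simulation and rank-product meta-analysis;
#' small-RNA simulation, miRNA DE calling and AGO1-enrichment filtering;
#' transcript/site simulation and target prediction; degradome simulation
#' and Category 0-4 validation; network assembly; structural
#' characterization. All artifacts are written to `cfg$out_dir` with the
#' configuration hash and seed stamped in a run log that also records
#' per-stage counts.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results (`degs`,
#'   `de_mirnas`, `enriched`, `sites`, `validated`, `network`, `report`,
#'   `truth`, `out_dir`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sc <- cfg$scenario
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("stressgrn pipeline; seed=", sc$seed,
                        "; config_hash=", config_hash(cfg)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  expr <- stage("expression", simulate_expression_studies(sc))
  de <- stage("meta_de",
              meta_de(expr$studies, n_perm = cfg$n_perm, seed = sc$seed,
                      threshold = cfg$pfp_threshold))
  degs <- de$calls
  log_lines <- c(log_lines, paste0("meta_de: ", nrow(degs), " DEGs at PFP<",
                                   cfg$pfp_threshold))

  srna <- stage("srna", simulate_srna_libraries(sc))
  libs <- srna$libraries
  kind <- vapply(libs, `[[`, "", "kind")
  de_mirnas <- stage("mirna_de",
    call_de_mirnas(libs[kind == "stress"], libs[kind == "control"],
                   min_abs_log2fc = cfg$de_min_lfc, alpha = cfg$de_alpha,
                   stress_label = sc$stress_label))
  enriched <- stage("ago1_filter",
    ago1_enrichment_filter(de_mirnas, libs[kind == "ago1"],
                           min_rpm = cfg$rpm_threshold))
  log_lines <- c(log_lines,
                 paste0("mirna_de: ", nrow(de_mirnas), " DE miRNAs; ",
                        length(enriched), " AGO1-enriched"))

  txs <- stage("transcripts", simulate_transcripts_and_sites(sc))
  if (!is.null(cfg$mirna_fasta)) txs$mirnas <- load_fasta(cfg$mirna_fasta)
  if (!is.null(cfg$transcript_fasta))
    txs$transcripts <- load_fasta(cfg$transcript_fasta)
  sites <- stage("predict_targets",
    predict_targets(txs$mirnas, txs$transcripts,
                    cutoff = cfg$expectation_cutoff))
  log_lines <- c(log_lines, paste0("predict_targets: ", nrow(sites),
                                   " candidate sites"))

  deg_lib <- if (!is.null(cfg$degradome_tsv))
    read_degradome_tsv(cfg$degradome_tsv)
  else stage("degradome",
             simulate_degradome(txs$transcripts, txs$truth, sc))$library
  val <- stage("validate_degradome", validate_targets(sites, deg_lib))
  log_lines <- c(log_lines,
                 paste0("validate_degradome: ", nrow(val$validated),
                        " validated interactions (",
                        paste(paste0("cat", names(val$summary), "=",
                                     val$summary), collapse = ", "), ")"))

  # map the validated miRNA site ids onto the count-library miRNA namespace
  # (synthetic sequence miRNAs mirK correspond to count-library mK)
  validated <- val$validated
  if (is.null(cfg$mirna_fasta) && nrow(validated))
    validated$mirna_id <- sub("^mir", "m", validated$mirna_id)

  reg <- if (!is.null(cfg$regulon_csv)) {
    tab <- load_edge_table(cfg$regulon_csv)
    list(regulon = data.frame(source_id = tab$source_id,
                              target_id = tab$target_id,
                              target_type = tab$target_type,
                              stringsAsFactors = FALSE),
         mimics = data.frame(mimic_id = character(),
                             mirna_id = character()))
  } else stage("regulon",
               simulate_regulon_tables(sc, de_mirnas = de_mirnas$mirna_id))
  net <- stage("assemble_network",
    assemble_network(validated, enriched, regulon_edges = reg$regulon,
                     mimic_edges = reg$mimics, degs = degs,
                     tf_ids = paste0("TF", seq_len(sc$n_tfs)),
                     stress_label = sc$stress_label))
  ns <- summarize_network(net)
  log_lines <- c(log_lines,
                 paste0("assemble_network: ", ns$n_nodes, " nodes, ",
                        ns$n_edges, " edges"))

  report <- NULL
  if (cfg$run_metrics && ns$n_edges >= 2) {
    report <- stage("topology_report",
                    topology_report(net, er_reps = cfg$er_reps,
                                    seed = sc$seed, fit_degree_tail = FALSE))
    log_lines <- c(log_lines,
                   paste0("topology_report: largest SCC ",
                          report$largest_scc, ", diameter ",
                          report$diameter))
  }

  out <- function(f) file.path(cfg$out_dir, f)
  utils::write.table(degs, out("degs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(de_mirnas, out("de_mirnas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(enriched, out("ago1_enriched.txt"))
  utils::write.table(sites, out("target_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(validated, out("validated_interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_edge_table(net, out("network.csv"))
  export_graphml(net, out("network.graphml"))
  if (!is.null(report))
    write_topology_report(report, out("topology.json"), out("topology.tsv"))
  writeLines(log_lines, out("pipeline.log"))

  invisible(list(degs = degs, de_mirnas = de_mirnas, enriched = enriched,
                 sites = sites, validated = validated, network = net,
                 report = report,
                 truth = list(expression = expr$truth, srna = srna$truth,
                              sites = txs$truth),
                 out_dir = cfg$out_dir))
}
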