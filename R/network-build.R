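.node_types <- c("TF", "miRNA", "gene", "targetMimic")
.edge_types <- c("TF->TF", "TF->gene", "TF->miRNA", "miRNA->gene",
                 "mimic->miRNA")

#' Assemble the stress-specific heterogeneous regulatory network
#'
#' Combines the five relationship sources into one directed graph:
#' \itemize{
#'   \item miRNA->gene edges from degradome-validated interactions,
#'     restricted to AGO1-enriched miRNAs (a validated miRNA->TF interaction
#'     keeps edge type miRNA->gene with target type TF);
#'   \item TF->gene / TF->miRNA / TF->TF edges from the regulon table,
#'     restricted to targets that are stress-responsive (differentially
#'     expressed genes or enriched miRNAs) or TFs on a regulatory path to
#'     one (closure of depth `closure_depth`);
#'   \item mimic->miRNA edges restricted to enriched miRNAs.
#' }
#' Duplicate `(source, target, edge_type)` triples are collapsed and orphan
#' nodes dropped. Node types follow the precedence TF > miRNA >
#' targetMimic > gene.
#'
#' @param validated data.frame of validated interactions (needs `mirna_id`,
#'   `transcript_id`), e.g. `validate_targets(...)$validated`.
#' @param enriched_mirnas character vector of AGO1-enriched miRNA ids.
#' @param regulon_edges data.frame `source_id`, `target_id`, `target_type`
#'   (TF regulons), or `NULL`.
#' @param mimic_edges data.frame `mimic_id`, `mirna_id`, or `NULL`.
#' @param degs data.frame of DEG calls with a `gene_id` column, or `NULL`.
#' @param tf_ids character vector naming the transcription factors.
#' @param stress_label stress condition of the network.
#' @param closure_depth how many TF->TF hops upstream of a stress-responsive
#'   node are retained (default 1).
#' @return a `reg_network`: list with `nodes` (data.frame `id`, `type`),
#'   `edges` (data.frame `source_id`, `source_type`, `target_id`,
#'   `target_type`, `edge_type`) and `stress_label`.
#' @export
assemble_network <- function(validated, enriched_mirnas,
                             regulon_edges = NULL, mimic_edges = NULL,
                             degs = NULL, tf_ids = character(),
                             stress_label = "none", closure_depth = 1L) {
  edges <- data.frame(source_id = character(), source_type = character(),
                      target_id = character(), target_type = character(),
                      edge_type = character(), stringsAsFactors = FALSE)
  type_of <- function(ids, mirna_ids, mimic_ids) {
    ifelse(ids %in% tf_ids, "TF",
           ifelse(ids %in% mirna_ids, "miRNA",
                  ifelse(ids %in% mimic_ids, "targetMimic", "gene")))
  }
  mirna_ids <- unique(c(enriched_mirnas,
                        if (!is.null(validated)) validated$mirna_id,
                        if (!is.null(mimic_edges)) mimic_edges$mirna_id))
  mimic_ids <- if (!is.null(mimic_edges)) unique(mimic_edges$mimic_id)
               else character()

  if (!is.null(validated) && nrow(validated)) {
    keep <- validated[validated$mirna_id %in% enriched_mirnas, ,
                      drop = FALSE]
    if (nrow(keep))
      edges <- rbind(edges, data.frame(
        source_id = keep$mirna_id, source_type = "miRNA",
        target_id = keep$transcript_id,
        target_type = ifelse(keep$transcript_id %in% tf_ids, "TF", "gene"),
        edge_type = "miRNA->gene", stringsAsFactors = FALSE))
  }

  if (!is.null(mimic_edges) && nrow(mimic_edges)) {
    keep <- mimic_edges[mimic_edges$mirna_id %in% enriched_mirnas, ,
                        drop = FALSE]
    if (nrow(keep))
      edges <- rbind(edges, data.frame(
        source_id = keep$mimic_id, source_type = "targetMimic",
        target_id = keep$mirna_id, target_type = "miRNA",
        edge_type = "mimic->miRNA", stringsAsFactors = FALSE))
  }

  if (!is.null(regulon_edges) && nrow(regulon_edges)) {
    if (!all(regulon_edges$target_type %in% c("TF", "gene", "miRNA")))
      stop("regulon edge with unknown target type at row ",
           which(!regulon_edges$target_type %in%
                   c("TF", "gene", "miRNA"))[1])
    responsive <- unique(c(if (!is.null(degs)) degs$gene_id,
                           enriched_mirnas,
                           edges$target_id, edges$source_id))
    keep <- regulon_edges$target_id %in% responsive
    for (d in seq_len(closure_depth)) {
      on_path <- unique(regulon_edges$source_id[keep])
      keep <- keep | (regulon_edges$target_type == "TF" &
                        regulon_edges$target_id %in% on_path)
    }
    reg <- regulon_edges[keep, , drop = FALSE]
    if (nrow(reg))
      edges <- rbind(edges, data.frame(
        source_id = reg$source_id, source_type = "TF",
        target_id = reg$target_id, target_type = reg$target_type,
        edge_type = paste0("TF->", ifelse(reg$target_type == "TF", "TF",
                                          ifelse(reg$target_type == "miRNA",
                                                 "miRNA", "gene"))),
        stringsAsFactors = FALSE))
  }

  edges <- edges[!duplicated(edges[, c("source_id", "target_id",
                                       "edge_type")]), , drop = FALSE]
  rownames(edges) <- NULL
  ids <- unique(c(edges$source_id, edges$target_id))
  nodes <- data.frame(id = ids,
                      type = type_of(ids, mirna_ids, mimic_ids),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, stress_label = stress_label),
            class = "reg_network")
}

#' Summarize a regulatory network
#'
#' @param net a `reg_network`.
#' @return list with `n_nodes`, `n_edges`, `node_types` (named counts for
#'   TF/miRNA/gene/targetMimic) and `edge_types` (named counts for the five
#'   relationship kinds).
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  node_types <- vapply(.node_types,
                       function(t) sum(net$nodes$type == t), integer(1))
  edge_types <- vapply(.edge_types,
                       function(t) sum(net$edges$edge_type == t), integer(1))
  list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
       node_types = node_types, edge_types = edge_types)
}

#' Convert a regulatory network to an igraph object
#'
#' @param net a `reg_network`.
#' @return directed [igraph::igraph] with vertex attribute `node_type` and
#'   edge attribute `edge_type`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  if (nrow(net$edges) == 0) {
    g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = TRUE)
    if (nrow(net$nodes)) {
      igraph::V(g)$name <- net$nodes$id
      igraph::V(g)$node_type <- net$nodes$type
    }
    return(g)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$source_id, to = net$edges$target_id,
               edge_type = net$edges$edge_type, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$nodes$id,
                          node_type = net$nodes$type,
                          stringsAsFactors = FALSE))
  g
}

#' Rebuild a regulatory network from an edge data.frame
#'
#' Inverse of the network's edge dump: re-assembling a network's own edges
#' reproduces it exactly (idempotence).
#'
#' @param edges data.frame with columns `source_id`, `source_type`,
#'   `target_id`, `target_type`, `edge_type`.
#' @param stress_label stress condition of the network.
#' @return a `reg_network`.
#' @export
network_from_edges <- function(edges, stress_label = "none") {
  need <- c("source_id", "source_type", "target_id", "target_type",
            "edge_type")
  if (!all(need %in% names(edges)))
    stop("missing edge columns: ",
         paste(setdiff(need, names(edges)), collapse = ", "))
  bad <- which(!edges$edge_type %in% .edge_types)
  if (length(bad))
    stop("illegal edge type '", edges$edge_type[bad[1]], "' at row ", bad[1])
  bad <- which(!edges$source_type %in% .node_types |
                 !edges$target_type %in% .node_types)
  if (length(bad))
    stop("illegal node type at row ", bad[1])
  edges <- edges[!duplicated(edges[, c("source_id", "target_id",
                                       "edge_type")]), need, drop = FALSE]
  rownames(edges) <- NULL
  prec <- c(TF = 1, miRNA = 2, targetMimic = 3, gene = 4)
  tab <- rbind(data.frame(id = edges$source_id, type = edges$source_type,
                          stringsAsFactors = FALSE),
               data.frame(id = edges$target_id, type = edges$target_type,
                          stringsAsFactors = FALSE))
  tab <- tab[order(tab$id, prec[tab$type]), ]
  tab <- tab[!duplicated(tab$id), ]
  rownames(tab) <- NULL
  structure(list(nodes = tab, edges = edges, stress_label = stress_label),
            class = "reg_network")
}
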