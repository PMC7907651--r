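#' Read a FASTA file
#'
#' Identifiers are the first whitespace-delimited header token; sequences
#' are uppercased and, on request, RNA `U` is normalized to `T`. Duplicate
#' identifiers and malformed leading content are rejected.
#'
#' @param path FASTA file path.
#' @param rna_to_dna normalize `U` to `T` (default `TRUE`).
#' @return named character vector of sequences.
#' @export
load_fasta <- function(path, rna_to_dna = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 50L)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first) || !startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA (no '>' header) at line ",
         if (is.na(first)) 1L else first, " of ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (rna_to_dna) seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) stop("sequences must be named")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Load a regulatory edge table from CSV
#'
#' Expects the standard download shape: `source_id`, `source_type`,
#' `target_id`, `target_type`, `interaction_type`, `stress`, `species`.
#' Node and interaction types are validated against the legal vocabularies;
#' offending row numbers are named in errors.
#'
#' @param path CSV path.
#' @return data.frame with columns `source_id`, `source_type`, `target_id`,
#'   `target_type`, `edge_type`, `stress`, `species`.
#' @export
load_edge_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_id", "source_type", "target_id", "target_type",
            "interaction_type", "stress", "species")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  bad <- which(!df$interaction_type %in% .edge_types)
  if (length(bad))
    stop("illegal interaction_type '", df$interaction_type[bad[1]],
         "' at row ", bad[1])
  bad <- which(!df$source_type %in% .node_types |
                 !df$target_type %in% .node_types)
  if (length(bad))
    stop("illegal node type at row ", bad[1])
  data.frame(source_id = df$source_id, source_type = df$source_type,
             target_id = df$target_id, target_type = df$target_type,
             edge_type = df$interaction_type, stress = df$stress,
             species = df$species, stringsAsFactors = FALSE)
}

#' Write a regulatory network's edges to CSV
#'
#' @param net a `reg_network`.
#' @param path output CSV path.
#' @param species species label column.
#' @return invisibly, `path`.
#' @export
write_edge_table <- function(net, path, species = "Oryza sativa") {
  stopifnot(inherits(net, "reg_network"))
  df <- data.frame(source_id = net$edges$source_id,
                   source_type = net$edges$source_type,
                   target_id = net$edges$target_id,
                   target_type = net$edges$target_type,
                   interaction_type = net$edges$edge_type,
                   stress = net$stress_label, species = species,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a regulatory network to GraphML
#'
#' Nodes carry a `node_type` attribute and edges an `edge_type` attribute.
#'
#' @param net a `reg_network` or igraph.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_graphml <- function(net, path) {
  g <- as_graph(net)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a GraphML network
#'
#' @param path GraphML path.
#' @return an [igraph::igraph] with `node_type` / `edge_type` attributes as
#'   present in the file.
#' @export
import_graphml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  igraph::read_graph(path, format = "graphml")
}

#' Read an expression study from TSV files
#'
#' @param matrix_path TSV of the genes x samples log2-intensity matrix (first
#'   column = gene id, header = sample names).
#' @param samplesheet_path TSV with columns `sample` and `group`
#'   (case/control).
#' @param study_id study identifier.
#' @return an [expression_study()].
#' @export
read_expression_study <- function(matrix_path, samplesheet_path, study_id) {
  if (!file.exists(matrix_path)) stop("no such file: ", matrix_path)
  if (!file.exists(samplesheet_path))
    stop("no such file: ", samplesheet_path)
  m <- utils::read.delim(matrix_path, row.names = 1, check.names = FALSE)
  sheet <- utils::read.delim(samplesheet_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(sheet)))
    stop("sample sheet needs 'sample' and 'group' columns")
  miss <- setdiff(colnames(m), sheet$sample)
  if (length(miss))
    stop("samples missing from sheet: ", paste(miss, collapse = ", "))
  grp <- sheet$group[match(colnames(m), sheet$sample)]
  expression_study(study_id, as.matrix(m), grp)
}

#' Write an expression study to TSV
#'
#' @param study an [expression_study()].
#' @param matrix_path,samplesheet_path output paths.
#' @return invisibly, `matrix_path`.
#' @export
write_expression_study <- function(study, matrix_path, samplesheet_path) {
  utils::write.table(data.frame(gene_id = rownames(study$matrix),
                                study$matrix, check.names = FALSE),
                     matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(study$matrix),
                                group = study$group),
                     samplesheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read a degradome tag table
#'
#' TSV with columns `transcript_id`, `position`, `count` (1-based
#' coordinates).
#'
#' @param path TSV path.
#' @param library_id identifier of the library.
#' @return a `degradome_library`.
#' @export
read_degradome_tsv <- function(path, library_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "count")
  if (!all(need %in% names(df)))
    stop("degradome TSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$count < 1)) stop("degradome counts must be >= 1")
  profiles <- lapply(split(df, df$transcript_id), function(x) {
    v <- x$count
    names(v) <- x$position
    v
  })
  structure(list(library_id = library_id %||% basename(path),
                 profiles = profiles, unmapped = 0L),
            class = "degradome_library")
}

#' Write a degradome library to TSV
#'
#' @param lib a `degradome_library`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_degradome_tsv <- function(lib, path) {
  stopifnot(inherits(lib, "degradome_library"))
  rows <- do.call(rbind, lapply(names(lib$profiles), function(tx) {
    data.frame(transcript_id = tx,
               position = as.integer(names(lib$profiles[[tx]])),
               count = unname(lib$profiles[[tx]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(transcript_id = character(), position = integer(),
                       count = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
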