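#' Reads-per-million normalization
#'
#' `RPM = count * 1e6 / total_mapped`.
#'
#' @param lib a [smallrna_library()].
#' @return named numeric vector of RPM values per miRNA.
#' @export
rpm_normalize <- function(lib) {
  stopifnot(inherits(lib, "smallrna_library"))
  if (lib$total_mapped <= 0) stop("total_mapped must be > 0")
  lib$counts * 1e6 / lib$total_mapped
}

#' Differential expression of miRNAs by pooled exact binomial test
#'
#' A simple documented DE caller: counts are pooled across the libraries of
#' each arm; each miRNA's pooled case count is tested two-sidedly with an
#' exact binomial test against the library-size-proportional expectation
#' (`p = depth_case / (depth_case + depth_control)`). The fold change is
#' computed on pooled RPM with a pseudo-count of 0.5 RPM (used for the fold
#' change only, never for the test). A miRNA is called when `p < alpha` and
#' `|log2FC| >= min_abs_log2fc`.
#'
#' @param case_libs,control_libs lists of [smallrna_library()] objects (at
#'   least one per arm).
#' @param min_abs_log2fc fold-change floor (default 1).
#' @param alpha significance threshold (default 0.05).
#' @param stress_label label attached to the calls.
#' @return data.frame `mirna_id`, `log2fc`, `direction`, `p`, `stress_label`
#'   of called miRNAs.
#' @export
call_de_mirnas <- function(case_libs, control_libs, min_abs_log2fc = 1,
                           alpha = 0.05, stress_label = "none") {
  if (length(case_libs) < 1 || length(control_libs) < 1)
    stop("need at least one library per arm")
  pool <- function(libs) {
    ids <- unique(unlist(lapply(libs, function(l) names(l$counts))))
    cnt <- numeric(length(ids))
    names(cnt) <- ids
    for (l in libs) cnt[names(l$counts)] <- cnt[names(l$counts)] + l$counts
    list(counts = cnt,
         depth = sum(vapply(libs, `[[`, numeric(1), "total_mapped")))
  }
  ca <- pool(case_libs)
  co <- pool(control_libs)
  ids <- union(names(ca$counts), names(co$counts))
  x_ca <- ifelse(ids %in% names(ca$counts), ca$counts[ids], 0)
  x_co <- ifelse(ids %in% names(co$counts), co$counts[ids], 0)
  rpm_ca <- x_ca * 1e6 / ca$depth
  rpm_co <- x_co * 1e6 / co$depth
  lfc <- log2((rpm_ca + 0.5) / (rpm_co + 0.5))
  p_exp <- ca$depth / (ca$depth + co$depth)
  pval <- vapply(seq_along(ids), function(i) {
    tot <- x_ca[i] + x_co[i]
    if (tot == 0) return(1)
    stats::binom.test(x_ca[i], tot, p = p_exp)$p.value
  }, numeric(1))
  keep <- pval < alpha & abs(lfc) >= min_abs_log2fc
  data.frame(mirna_id = ids[keep], log2fc = lfc[keep],
             direction = ifelse(lfc[keep] > 0, "up", "down"),
             p = pval[keep], stress_label = rep(stress_label, sum(keep)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' AGO1-enrichment filter for differentially expressed miRNAs
#'
#' Keeps a DE miRNA if and only if there exists an AGO1-associated library
#' in which it is both detectable (raw count > 0) and accumulates at three
#' reads per million or higher. Both conditions must hold in the same
#' library; the 3-RPM bound is inclusive.
#'
#' @param de data.frame of DE miRNAs with a `mirna_id` column (as from
#'   [call_de_mirnas()]), or a character vector of miRNA ids.
#' @param ago1_libs list of AGO1 [smallrna_library()] objects (at least one).
#' @param min_rpm accumulation threshold in RPM (default 3).
#' @return character vector: the AGO1-enriched subset of the DE miRNAs.
#' @export
ago1_enrichment_filter <- function(de, ago1_libs, min_rpm = 3) {
  if (length(ago1_libs) < 1) stop("need at least one AGO1 library")
  ids <- if (is.data.frame(de)) de$mirna_id else as.character(de)
  passes <- vapply(ids, function(id) {
    any(vapply(ago1_libs, function(l) {
      cnt <- l$counts[id]
      !is.na(cnt) && cnt > 0 && (cnt * 1e6 / l$total_mapped) >= min_rpm
    }, logical(1)))
  }, logical(1))
  unname(ids[passes])
}
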