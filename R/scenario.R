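#' Scenario configuration for the synthetic-data generators
#'
#' A `scenario_config` bundles every parameter the synthetic generators need:
#' multi-study expression simulation, negative-binomial small-RNA libraries
#' (stress, control and AGO1-associated), transcripts with planted miRNA
#' complementary sites, degradome tag profiles with planted cleavage
#' categories, and TF regulon / target-mimic edge tables. A fixed `seed`
#' makes every generator byte-reproducible; each generator draws from its own
#' sub-seeded stream so adding one never perturbs another.
#'
#' @param seed integer master seed (< 2^31).
#' @param n_genes number of genes in the expression universe.
#' @param n_studies number of independent case/control studies per stress.
#' @param n_replicates samples per arm within a study.
#' @param frac_de fraction of genes (and miRNAs) planted as differentially
#'   expressed, in `[0, 1]`.
#' @param effect_size mean |log2 fold change| of planted DE entities.
#' @param noise_sd within-study Gaussian standard deviation of log2
#'   intensities.
#' @param n_mirnas number of miRNAs.
#' @param library_size expected total mapped reads per small-RNA library.
#' @param nb_dispersion negative-binomial dispersion of counts (0 gives the
#'   Poisson limit).
#' @param n_transcripts number of background transcripts.
#' @param transcript_len transcript length in nucleotides.
#' @param site_plan list of planted-site descriptions; each element is a list
#'   with optional fields `mismatch_pos` (integer vector of miRNA positions),
#'   `gu_pos` (integer vector of miRNA positions carrying G:U wobbles) and
#'   `category` (planted degradome category, one of 0:4 or `NA` for a site
#'   with no degradome signal).
#' @param regulon_density expected out-degree of a transcription factor in the
#'   simulated regulon table.
#' @param n_tfs number of transcription factors.
#' @param mirna_len miRNA length in nucleotides (plant miRNAs are 20-24 nt).
#' @param n_ago1_libs number of AGO1-associated libraries.
#' @param stress_label stress condition label for the simulated libraries.
#'
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_genes = 1000L,
                            n_studies = 3L,
                            n_replicates = 3L,
                            frac_de = 0.05,
                            effect_size = 2,
                            noise_sd = 0.5,
                            n_mirnas = 200L,
                            library_size = 1e6,
                            nb_dispersion = 0.1,
                            n_transcripts = 50L,
                            transcript_len = 500L,
                            site_plan = list(),
                            regulon_density = 5,
                            n_tfs = 20L,
                            mirna_len = 21L,
                            n_ago1_libs = 3L,
                            stress_label = "drought") {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_studies = as.integer(n_studies), n_replicates = as.integer(n_replicates),
    frac_de = frac_de, effect_size = effect_size, noise_sd = noise_sd,
    n_mirnas = as.integer(n_mirnas), library_size = library_size,
    nb_dispersion = nb_dispersion, n_transcripts = as.integer(n_transcripts),
    transcript_len = as.integer(transcript_len), site_plan = site_plan,
    regulon_density = regulon_density, n_tfs = as.integer(n_tfs),
    mirna_len = as.integer(mirna_len), n_ago1_libs = as.integer(n_ago1_libs),
    stress_label = stress_label
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  counts <- c("n_genes", "n_studies", "n_replicates", "n_mirnas",
              "n_transcripts", "transcript_len", "n_tfs", "mirna_len",
              "n_ago1_libs")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("configuration error: '", f, "' must be a count >= 1")
  }
  if (cfg$frac_de < 0 || cfg$frac_de > 1)
    stop("configuration error: 'frac_de' must lie in [0, 1]")
  if (cfg$noise_sd < 0)
    stop("configuration error: 'noise_sd' must be >= 0")
  if (cfg$nb_dispersion < 0)
    stop("configuration error: 'nb_dispersion' must be >= 0")
  if (cfg$library_size < cfg$n_mirnas)
    stop("configuration error: 'library_size' must be >= 'n_mirnas'")
  if (cfg$transcript_len < cfg$mirna_len + 2L)
    stop("configuration error: 'transcript_len' must be >= miRNA length + 2")
  if (length(cfg$site_plan) > cfg$n_transcripts)
    stop("configuration error: more planted sites than transcripts")
  if (cfg$regulon_density < 0)
    stop("configuration error: 'regulon_density' must be >= 0")
  invisible(cfg)
}

# Fixed sub-seed schedule: one RNG stream per generator so the draws of one
# generator never shift those of another. Offsets are arbitrary but frozen.
.subseed_offsets <- c(expression = 101L, srna = 211L, transcripts = 307L,
                      degradome = 401L, regulon = 503L)

set_subseed <- function(cfg, which) {
  off <- .subseed_offsets[[which]]
  set.seed((abs(cfg$seed) + off) %% .Machine$integer.max)
}
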