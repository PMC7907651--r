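#' Simulate multi-study case/control expression data
#'
#' Generates `cfg$n_studies` independent studies, each a genes x samples
#' matrix of post-normalization log2 intensities with `cfg$n_replicates`
#' case and control samples. A fraction `cfg$frac_de` of genes is planted as
#' differentially expressed: cases are shifted by +/- `cfg$effect_size` with
#' the same direction in every study (conserved response). Gaussian noise
#' with standard deviation `cfg$noise_sd` is added throughout.
#'
#' @param cfg a [scenario_config()].
#' @return a list with `studies` (list of expression studies, each carrying
#'   `study_id`, `matrix`, `group`) and `truth` (data.frame `gene_id`,
#'   `direction` of planted DE genes; zero rows for a null scenario).
#' @export
simulate_expression_studies <- function(cfg) {
  validate_scenario_config(cfg)
  set_subseed(cfg, "expression")
  genes <- paste0("g", seq_len(cfg$n_genes))
  n_de <- round(cfg$frac_de * cfg$n_genes)
  n_up <- ceiling(n_de / 2)
  de_genes <- if (n_de > 0) sample(genes, n_de) else character()
  direction <- c(rep("up", n_up), rep("down", n_de - n_up))
  shift <- numeric(cfg$n_genes)
  names(shift) <- genes
  shift[de_genes] <- ifelse(direction == "up", cfg$effect_size,
                            -cfg$effect_size)

  r <- cfg$n_replicates
  group <- c(rep("control", r), rep("case", r))
  studies <- lapply(seq_len(cfg$n_studies), function(s) {
    baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 1)
    m <- matrix(stats::rnorm(cfg$n_genes * 2L * r, sd = cfg$noise_sd),
                nrow = cfg$n_genes)
    m <- m + baseline
    m[, group == "case"] <- m[, group == "case"] + shift
    dimnames(m) <- list(genes, paste0("s", s, "_", group, "_",
                                      c(seq_len(r), seq_len(r))))
    expression_study(paste0("study", s), m, group)
  })
  truth <- data.frame(gene_id = de_genes, direction = direction,
                      stringsAsFactors = FALSE)
  list(studies = studies, truth = truth)
}

#' Construct an expression-study object
#'
#' @param study_id study identifier.
#' @param matrix genes x samples matrix of log2 intensities with unique
#'   rownames.
#' @param group per-sample labels, each `"case"` or `"control"`; at least one
#'   of each.
#' @return a list of class `expression_study`.
#' @export
expression_study <- function(study_id, matrix, group) {
  if (ncol(matrix) != length(group))
    stop("group labels must match the number of sample columns")
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (!any(group == "case") || !any(group == "control"))
    stop("need at least one case and one control sample")
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stop("gene identifiers (rownames) must be present and unique")
  structure(list(study_id = study_id, matrix = matrix, group = group),
            class = "expression_study")
}

#' Construct a small-RNA library object
#'
#' @param library_id library identifier.
#' @param kind one of `"stress"`, `"control"`, `"ago1"`.
#' @param counts named vector of raw read counts per miRNA (all `>= 0`).
#' @param total_mapped total mapped reads (`> 0`, `>= sum(counts)`).
#' @param stress_label one of `"cold"`, `"drought"`, `"salt"`, `"none"`.
#' @return a list of class `smallrna_library`.
#' @export
smallrna_library <- function(library_id, kind, counts, total_mapped,
                             stress_label = "none") {
  kind <- match.arg(kind, c("stress", "control", "ago1"))
  stress_label <- match.arg(stress_label,
                            c("cold", "drought", "salt", "none"))
  if (is.null(names(counts)) || anyDuplicated(names(counts)))
    stop("counts must be uniquely named by miRNA id")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  if (sum(counts) > total_mapped)
    stop("sum of counts exceeds total_mapped")
  structure(list(library_id = library_id, kind = kind, counts = counts,
                 total_mapped = total_mapped, stress_label = stress_label),
            class = "smallrna_library")
}

#' Simulate small-RNA libraries (stress, control and AGO1-associated)
#'
#' Counts are negative binomial around library-size-proportional means
#' (Poisson when `cfg$nb_dispersion == 0`). A fraction `cfg$frac_de` of
#' miRNAs carries a planted fold change of `2^cfg$effect_size` in the stress
#' arm. AGO1 libraries contain a designated detectable subset guaranteed to
#' reach >= 3 reads per million in at least one AGO1 library, with the
#' complement held below 3 RPM in all of them.
#'
#' @param cfg a [scenario_config()].
#' @return list with `libraries` (list of [smallrna_library()]) and `truth`
#'   (list with data.frame `mirnas` giving planted `direction`, and character
#'   vector `ago1_detectable`).
#' @export
simulate_srna_libraries <- function(cfg) {
  validate_scenario_config(cfg)
  set_subseed(cfg, "srna")
  mirnas <- paste0("m", seq_len(cfg$n_mirnas))
  w <- stats::rlnorm(cfg$n_mirnas, meanlog = 0, sdlog = 1.2)
  w <- w / sum(w)
  names(w) <- mirnas

  n_de <- round(cfg$frac_de * cfg$n_mirnas)
  n_up <- ceiling(n_de / 2)
  de <- if (n_de > 0) sample(mirnas, n_de) else character()
  dir <- c(rep("up", n_up), rep("down", n_de - n_up))
  fold <- rep(1, cfg$n_mirnas)
  names(fold) <- mirnas
  fold[de] <- 2^ifelse(dir == "up", cfg$effect_size, -cfg$effect_size)

  draw_counts <- function(mu) {
    cnt <- if (cfg$nb_dispersion == 0) stats::rpois(length(mu), mu)
           else stats::rnbinom(length(mu), mu = mu,
                               size = 1 / cfg$nb_dispersion)
    names(cnt) <- mirnas
    cnt
  }
  budget <- 0.9 * cfg$library_size  # headroom so counts never exceed depth
  make_lib <- function(id, kind, weights, stress_label) {
    cnt <- draw_counts(weights / sum(weights) * budget)
    if (sum(cnt) > cfg$library_size)
      cnt <- floor(cnt * (budget / sum(cnt)))
    smallrna_library(id, kind, cnt, cfg$library_size, stress_label)
  }

  libs <- list()
  for (i in seq_len(cfg$n_replicates))
    libs[[length(libs) + 1L]] <-
      make_lib(paste0("ctrl_", i), "control", w, cfg$stress_label)
  for (i in seq_len(cfg$n_replicates))
    libs[[length(libs) + 1L]] <-
      make_lib(paste0("stress_", i), "stress", w * fold, cfg$stress_label)

  # AGO1 libraries: a designated subset is forced to >= 3 RPM in every AGO1
  # library; the complement is capped strictly below 3 RPM.
  det_n <- max(1L, round(0.6 * cfg$n_mirnas))
  detectable <- sort(sample(mirnas, det_n))
  min_det <- ceiling(3 * cfg$library_size / 1e6)
  for (i in seq_len(cfg$n_ago1_libs)) {
    cnt <- draw_counts(w / sum(w) * budget)
    cnt[detectable] <- pmax(cnt[detectable], min_det)
    cnt[setdiff(mirnas, detectable)] <-
      pmin(cnt[setdiff(mirnas, detectable)], min_det - 1L)
    if (sum(cnt) > cfg$library_size)
      stop("configuration error: library_size too small to realize the ",
           "AGO1 detectability plan")
    libs[[length(libs) + 1L]] <-
      smallrna_library(paste0("ago1_", i), "ago1", cnt, cfg$library_size,
                       "none")
  }

  truth <- list(
    mirnas = data.frame(mirna_id = de, direction = dir,
                        stringsAsFactors = FALSE),
    ago1_detectable = detectable
  )
  list(libraries = libs, truth = truth)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  paste(rev(.complement[strsplit(seq, "")[[1]]]), collapse = "")
}

#' Simulate transcripts with planted miRNA complementary sites
#'
#' Generates random-background transcripts and one random miRNA per planted
#' site (plus extras up to `cfg$n_mirnas`, capped at 10 for scanning
#' scenarios). For each `cfg$site_plan` entry the reverse complement of a
#' miRNA -- optionally mutated with mismatches and G:U wobbles at stated
#' miRNA positions -- is embedded at a recorded 1-based coordinate of its own
#' transcript. The planted site's true expectation score and cleavage
#' position are recorded in the truth table.
#'
#' @param cfg a [scenario_config()]; `site_plan` entries are lists with
#'   optional `mismatch_pos`, `gu_pos` and `category` fields.
#' @return list with `transcripts` (named character vector), `mirnas` (named
#'   character vector) and `truth` (data.frame of planted sites:
#'   `mirna_id`, `transcript_id`, `start`, `end`, `cleavage_pos`,
#'   `expectation`, `category`).
#' @export
simulate_transcripts_and_sites <- function(cfg) {
  validate_scenario_config(cfg)
  set_subseed(cfg, "transcripts")
  L <- cfg$mirna_len
  n_plan <- length(cfg$site_plan)
  n_mir <- max(n_plan, min(cfg$n_mirnas, 10L))
  for (p in cfg$site_plan) {
    bad <- c(p$mismatch_pos, p$gu_pos)
    if (length(bad) && (any(bad < 1L) || any(bad > L)))
      stop("configuration error: site_plan positions outside the miRNA")
  }

  mirnas <- vapply(seq_len(n_mir), function(i) rand_seq(L), character(1))
  names(mirnas) <- paste0("mir", seq_len(n_mir))
  # force G or U at requested wobble positions so the wobble is realizable
  for (i in seq_len(n_plan)) {
    gu <- cfg$site_plan[[i]]$gu_pos
    if (length(gu)) {
      chars <- strsplit(mirnas[[i]], "")[[1]]
      chars[gu] <- sample(c("G", "T"), length(gu), replace = TRUE)
      mirnas[[i]] <- paste(chars, collapse = "")
    }
  }

  transcripts <- vapply(seq_len(cfg$n_transcripts),
                        function(i) rand_seq(cfg$transcript_len),
                        character(1))
  names(transcripts) <- paste0("t", seq_len(cfg$n_transcripts))

  truth <- data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      cleavage_pos = integer(), expectation = numeric(),
                      category = integer(), stringsAsFactors = FALSE)
  for (i in seq_len(n_plan)) {
    plan <- cfg$site_plan[[i]]
    mir_id <- names(mirnas)[i]
    mchars <- strsplit(mirnas[[i]], "")[[1]]
    site <- strsplit(revcomp(mirnas[[i]]), "")[[1]]
    # miRNA position p (5'->3') pairs with site position L - p + 1
    for (p in plan$gu_pos) {
      j <- L - p + 1L
      site[j] <- if (mchars[p] == "G") "T" else "G"
    }
    for (p in plan$mismatch_pos) {
      j <- L - p + 1L
      site[j] <- mchars[p]  # X:X never pairs (WC or wobble) for any base X
    }
    site_seq <- paste(site, collapse = "")
    tx_id <- names(transcripts)[i]
    start <- sample(seq(2L, cfg$transcript_len - L), 1L)
    tx <- strsplit(transcripts[[tx_id]], "")[[1]]
    tx[start:(start + L - 1L)] <- site
    transcripts[[tx_id]] <- paste(tx, collapse = "")
    sc <- score_duplex(mirnas[[i]], site_seq)
    truth <- rbind(truth, data.frame(
      mirna_id = mir_id, transcript_id = tx_id, start = start,
      end = start + L - 1L, cleavage_pos = start + L - 10L,
      expectation = sc$expectation,
      category = if (is.null(plan$category)) NA_integer_
                 else as.integer(plan$category),
      stringsAsFactors = FALSE))
  }
  list(transcripts = transcripts, mirnas = mirnas, truth = truth)
}

# Force a cleavage-site profile (full-length count vector) to realize a
# planted category at `pos`. Background stays in place; peaks are added so
# the category is computed, then verified by the classifier.
realize_category <- function(v, pos, category) {
  other <- setdiff(seq_along(v), pos)
  ensure_background <- function(v, k, value = 1) {
    occ <- other[v[other] > 0]
    need <- k - length(occ)
    if (need > 0) {
      free <- other[v[other] == 0]
      v[sample(free, need)] <- value
    }
    v
  }
  if (is.na(category)) {
    v[pos] <- 0
  } else if (category == 4L) {
    v[pos] <- 1
  } else if (category == 0L) {
    v[pos] <- max(v[other], 1) + 2
  } else if (category == 1L) {
    val <- max(v[other], 1) + 2
    v[pos] <- val
    v[sample(other, 1L)] <- val
  } else if (category == 2L) {
    v <- ensure_background(v, 3L)   # enough singletons to hold the median low
    v[sample(other[v[other] <= 1], 1L)] <- max(v) + 10
    v[pos] <- 2
  } else if (category == 3L) {
    v <- ensure_background(v, 3L)
    occ <- other[v[other] > 0]
    v[occ] <- v[occ] + 2            # lift the median above the site count
    v[sample(occ, 1L)] <- max(v) + 3
    v[pos] <- 2
  } else stop("unknown planted category: ", category)
  v
}

#' Simulate a degradome library realizing planted cleavage categories
#'
#' Lays down uniform low-level background 5'-tag counts (Poisson(0.05) per
#' transcript position), then places tags at each planted site's cleavage
#' position so that the site's classified category equals the planned one.
#' Every realized category is verified with [classify_cleavage_site()];
#' generation retries with fresh background and fails loudly if a plan is
#' unrealizable.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param sites planted-site truth table from
#'   [simulate_transcripts_and_sites()] (needs `transcript_id`,
#'   `cleavage_pos`, `category`).
#' @param cfg a [scenario_config()].
#' @param background_rate Poisson rate of background tags per position.
#' @return list with `library` (a `degradome_library`: `library_id`,
#'   `profiles` mapping transcript -> named position counts, `unmapped`) and
#'   `truth` (the realized per-site categories).
#' @export
simulate_degradome <- function(transcripts, sites, cfg,
                               background_rate = 0.05) {
  validate_scenario_config(cfg)
  if (nrow(sites) && !all(sites$transcript_id %in% names(transcripts)))
    stop("every planted site must lie on a provided transcript")
  set_subseed(cfg, "degradome")
  lens <- nchar(transcripts)
  profiles <- list()
  for (tx in names(transcripts)) {
    v <- stats::rpois(lens[[tx]], background_rate)
    rows <- sites[sites$transcript_id == tx, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      ok <- FALSE
      for (try in 1:10) {
        v2 <- realize_category(v, rows$cleavage_pos[i], rows$category[i])
        prof <- v2[v2 > 0]
        names(prof) <- which(v2 > 0)
        got <- classify_cleavage_site(prof, rows$cleavage_pos[i])
        want <- rows$category[i]
        if ((is.na(want) && is.na(got)) ||
            (!is.na(want) && !is.na(got) && got == want)) {
          v <- v2; ok <- TRUE; break
        }
        v <- stats::rpois(lens[[tx]], background_rate)
      }
      if (!ok)
        stop("unrealizable degradome category ", rows$category[i],
             " for site on ", tx, " at ", rows$cleavage_pos[i])
    }
    occ <- which(v > 0)
    prof <- v[occ]
    names(prof) <- occ
    if (length(prof)) profiles[[tx]] <- prof
  }
  lib <- structure(list(library_id = "degradome_1", profiles = profiles,
                        unmapped = 0L),
                   class = "degradome_library")
  list(library = lib, truth = sites)
}

#' Simulate TF regulon and target-mimic edge tables
#'
#' TF out-edges are drawn binomially against a pooled target universe of
#' genes, TFs and miRNAs so the expected out-degree is
#' `cfg$regulon_density`. The mimic table pairs endogenous target mimics
#' with miRNAs, guaranteeing at least one edge onto a supplied DE miRNA.
#'
#' @param cfg a [scenario_config()].
#' @param de_mirnas optional character vector of DE miRNA ids; when non-empty
#'   the mimic table is forced to cover at least one of them.
#' @return list with `regulon` (data.frame `source_id`, `target_id`,
#'   `target_type`), `mimics` (data.frame `mimic_id`, `mirna_id`) and `truth`
#'   (the same tables).
#' @export
simulate_regulon_tables <- function(cfg, de_mirnas = character()) {
  validate_scenario_config(cfg)
  set_subseed(cfg, "regulon")
  tfs <- paste0("TF", seq_len(cfg$n_tfs))
  genes <- paste0("g", seq_len(cfg$n_genes))
  mirnas <- paste0("m", seq_len(cfg$n_mirnas))
  pool <- c(genes, tfs, mirnas)
  type <- c(rep("gene", length(genes)), rep("TF", length(tfs)),
            rep("miRNA", length(mirnas)))
  p <- min(1, cfg$regulon_density / length(pool))
  src <- tgt <- tty <- character()
  for (tf in tfs) {
    hit <- which(stats::runif(length(pool)) < p & pool != tf)
    src <- c(src, rep(tf, length(hit)))
    tgt <- c(tgt, pool[hit])
    tty <- c(tty, type[hit])
  }
  regulon <- data.frame(source_id = src, target_id = tgt, target_type = tty,
                        stringsAsFactors = FALSE)

  n_mimic <- max(1L, round(0.05 * cfg$n_mirnas))
  mim_targets <- sample(mirnas, n_mimic)
  if (length(de_mirnas) && !any(mim_targets %in% de_mirnas))
    mim_targets[1L] <- sample(de_mirnas, 1L)
  mimics <- data.frame(mimic_id = paste0("eTM", seq_len(n_mimic)),
                       mirna_id = mim_targets, stringsAsFactors = FALSE)
  list(regulon = regulon, mimics = mimics,
       truth = list(regulon = regulon, mimics = mimics))
}
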