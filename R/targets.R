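normalize_nt <- function(seq) {
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGT]", s))
    stop("non-nucleotide characters in sequence: ", seq)
  s
}

# Per-position penalty: 0 Watson-Crick, 0.5 G:U wobble, 1 mismatch.
# miRNA base m pairs the transcript base t read antiparallel.
pair_state <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
        (m == "C" & t == "G") | (m == "G" & t == "C")
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, "match", ifelse(gu, "gu", "mismatch"))
}

.pair_penalty <- c(match = 0, gu = 0.5, mismatch = 1)
.seed_region <- 2:13  # penalties are doubled in the seed-pairing region

#' Score a miRNA:target-site duplex
#'
#' Gapless antiparallel alignment of a miRNA (5'->3') against a same-length
#' transcript window (5'->3'): miRNA position `i` pairs transcript window
#' position `L - i + 1`. Each position contributes 0 for a Watson-Crick
#' pair, 0.5 for a G:U wobble and 1 for a mismatch; contributions from the
#' seed region (miRNA positions 2-13) are doubled. The expectation score is
#' the total penalty (0 = perfect complementarity).
#'
#' @param mirna miRNA sequence, 5'->3', RNA or DNA alphabet (U and T are
#'   equivalent).
#' @param site_seq transcript window of the same length, 5'->3'.
#' @return list with `expectation` (numeric penalty) and `alignment`
#'   (character vector of per-miRNA-position states in
#'   `match`/`gu`/`mismatch`).
#' @export
score_duplex <- function(mirna, site_seq) {
  m <- strsplit(normalize_nt(mirna), "")[[1]]
  s <- strsplit(normalize_nt(site_seq), "")[[1]]
  if (length(m) != length(s))
    stop("miRNA and site must have equal length in gapless mode")
  L <- length(m)
  states <- pair_state(m, s[L - seq_len(L) + 1L])
  pen <- .pair_penalty[states]
  pen[.seed_region[.seed_region <= L]] <-
    2 * pen[.seed_region[.seed_region <= L]]
  list(expectation = sum(pen), alignment = unname(states))
}

#' Predict miRNA target sites on transcripts
#'
#' Slides a window of miRNA length along each transcript (forward strand
#' only; transcripts are sense mRNA), scores every window with
#' [score_duplex()] and reports sites with expectation `<= cutoff`. The
#' cleavage position is the transcript coordinate paired with miRNA
#' position 10 (AGO slices its target between the bases opposite miRNA
#' positions 10 and 11).
#'
#' @param mirnas named character vector of miRNA sequences (lengths 18-26).
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum expectation score (default 5.0).
#' @return data.frame of sites sorted by (transcript, start): `mirna_id`,
#'   `transcript_id`, `start`, `end` (1-based inclusive), `expectation`,
#'   `cleavage_pos`, `alignment` (state string, one symbol per miRNA
#'   position: `|` match, `o` G:U, `x` mismatch).
#' @export
predict_targets <- function(mirnas, transcripts, cutoff = 5.0) {
  if (is.null(names(mirnas)) || is.null(names(transcripts)))
    stop("mirnas and transcripts must be named")
  bad_len <- nchar(mirnas) < 18 | nchar(mirnas) > 26
  if (any(bad_len))
    stop("miRNA length outside 18-26 nt: ",
         paste(names(mirnas)[bad_len], collapse = ", "))
  sym <- c(match = "|", gu = "o", mismatch = "x")
  tx_chars <- lapply(transcripts, function(s)
    strsplit(normalize_nt(s), "")[[1]])
  out <- list()
  for (mi in names(mirnas)) {
    m <- strsplit(normalize_nt(mirnas[[mi]]), "")[[1]]
    L <- length(m)
    seed <- .seed_region[.seed_region <= L]
    for (ti in names(transcripts)) {
      s <- tx_chars[[ti]]
      n_win <- length(s) - L + 1L
      if (n_win < 1L) next
      # accumulate penalties across windows, vectorized over window starts
      e <- numeric(n_win)
      for (i in seq_len(L)) {
        j <- L - i + 1L  # site position paired with miRNA position i
        pen <- .pair_penalty[pair_state(m[i], s[seq_len(n_win) + j - 1L])]
        if (i %in% seed) pen <- 2 * pen
        e <- e + pen
      }
      hits <- which(e <= cutoff)
      for (w in hits) {
        site <- s[w:(w + L - 1L)]
        states <- pair_state(m, site[L - seq_len(L) + 1L])
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = mi, transcript_id = ti, start = w, end = w + L - 1L,
          expectation = e[w], cleavage_pos = w + L - 10L,
          alignment = paste(sym[states], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), cleavage_pos = integer(),
                      alignment = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$start, res$mirna_id), ]
  rownames(res) <- NULL
  res
}
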