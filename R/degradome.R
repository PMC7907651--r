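#' Map degradome 5'-end tags onto transcripts
#'
#' Sequence tags are located by exact substring match on the sense strand of
#' each transcript; a tag increments the count at its 5'-most matching
#' coordinate of every transcript it matches (once per transcript). Tags may
#' also be given pre-mapped as `(transcript_id, position, count)` rows.
#' Tags matching no transcript are tallied in the `unmapped` counter.
#'
#' @param tags either a character vector of tag sequences or a data.frame
#'   with columns `transcript_id`, `position` and optionally `count`.
#' @param transcripts named character vector of transcript sequences.
#' @param library_id identifier for the resulting library.
#' @return a `degradome_library`: `library_id`, `profiles` (per transcript a
#'   named vector position -> tag count, occupied positions only) and
#'   `unmapped`.
#' @export
map_degradome_tags <- function(tags, transcripts, library_id = "degradome") {
  profiles <- lapply(transcripts, function(x) numeric(0))
  unmapped <- 0L
  add <- function(profiles, tx, pos, n = 1) {
    key <- as.character(pos)
    cur <- profiles[[tx]]
    cur[key] <- if (key %in% names(cur)) cur[key] + n else n
    profiles[[tx]] <- cur
    profiles
  }
  if (is.data.frame(tags)) {
    if (!all(c("transcript_id", "position") %in% names(tags)))
      stop("pre-mapped tags need 'transcript_id' and 'position' columns")
    cnt <- if ("count" %in% names(tags)) tags$count else rep(1, nrow(tags))
    for (i in seq_len(nrow(tags))) {
      tx <- tags$transcript_id[i]
      if (!tx %in% names(transcripts)) { unmapped <- unmapped + 1L; next }
      if (tags$position[i] < 1 ||
          tags$position[i] > nchar(transcripts[[tx]]))
        stop("tag position outside transcript ", tx, ": ",
             tags$position[i])
      profiles <- add(profiles, tx, tags$position[i], cnt[i])
    }
  } else {
    if (length(tags) == 0)
      warning("empty tag set: returning an empty degradome library")
    for (tag in tags) {
      hit <- FALSE
      for (tx in names(transcripts)) {
        pos <- regexpr(tag, transcripts[[tx]], fixed = TRUE)
        if (pos > 0) {
          profiles <- add(profiles, tx, as.integer(pos))
          hit <- TRUE
        }
      }
      if (!hit) unmapped <- unmapped + 1L
    }
  }
  profiles <- profiles[vapply(profiles, length, integer(1)) > 0]
  structure(list(library_id = library_id, profiles = profiles,
                 unmapped = unmapped),
            class = "degradome_library")
}

#' Classify a predicted cleavage site against a degradome profile
#'
#' CleaveLand-style categories, computed from the tag count `t` at the
#' cleavage position, the maximum `M` and median `med` over the transcript's
#' occupied positions, and the number `u` of positions attaining `M`:
#' \itemize{
#'   \item `NA` (no evidence) if `t = 0`;
#'   \item Category 4 if `t = 1` (only one raw tag at the position);
#'   \item Category 0 if `t > 1`, `t = M` and the maximum is unique;
#'   \item Category 1 if `t > 1`, `t = M` and more than one position attains
#'     the maximum;
#'   \item Category 2 if `t > 1`, `t < M` and `t > med`;
#'   \item Category 3 if `t > 1` and `t <= med`.
#' }
#' The median is taken over occupied positions only (count >= 1).
#'
#' @param profile named numeric vector mapping occupied 1-based positions to
#'   tag counts (all counts >= 1); may be empty.
#' @param cleavage_pos 1-based transcript coordinate of the predicted
#'   cleavage site.
#' @return integer category in 0:4, or `NA` when no tag lies at the site.
#' @export
classify_cleavage_site <- function(profile, cleavage_pos) {
  if (length(profile) && any(profile < 1))
    stop("profile counts must be >= 1 at occupied positions")
  t <- profile[as.character(cleavage_pos)]
  t <- if (is.na(t) || length(t) == 0) 0 else unname(t)
  if (t == 0) return(NA_integer_)
  if (t == 1) return(4L)
  m <- max(profile)
  med <- stats::median(profile)
  u <- sum(profile == m)
  if (t == m) {
    if (u == 1L) return(0L) else return(1L)
  }
  if (t > med) return(2L)
  3L
}

#' Validate predicted target sites against degradome libraries
#'
#' Each predicted site is classified against every degradome library with
#' [classify_cleavage_site()]; the best (lowest-numbered) category across
#' libraries is retained. Sites with no tag at the cleavage position in any
#' library are excluded.
#'
#' @param sites data.frame of predicted sites from [predict_targets()].
#' @param libs a `degradome_library` or list of them.
#' @return list with `validated` (the input site rows plus `category`,
#'   `library_id`, `tags_at_site`, `transcript_max`, `transcript_median`,
#'   `n_max_positions`), `summary` (named count per category "0".."4"),
#'   `n_genes` and `n_mirnas` (distinct validated targets and miRNAs).
#' @export
validate_targets <- function(sites, libs) {
  if (inherits(libs, "degradome_library")) libs <- list(libs)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    best <- NULL
    for (lib in libs) {
      prof <- lib$profiles[[sites$transcript_id[i]]]
      if (is.null(prof)) next
      cat <- classify_cleavage_site(prof, sites$cleavage_pos[i])
      if (is.na(cat)) next
      if (is.null(best) || cat < best$category) {
        t <- unname(prof[as.character(sites$cleavage_pos[i])])
        best <- cbind(sites[i, , drop = FALSE], data.frame(
          category = cat, library_id = lib$library_id, tags_at_site = t,
          transcript_max = max(prof),
          transcript_median = stats::median(prof),
          n_max_positions = sum(prof == max(prof)),
          stringsAsFactors = FALSE))
      }
    }
    if (!is.null(best)) rows[[length(rows) + 1L]] <- best
  }
  validated <- if (length(rows)) do.call(rbind, rows) else
    cbind(sites[0, , drop = FALSE],
          data.frame(category = integer(), library_id = character(),
                     tags_at_site = numeric(), transcript_max = numeric(),
                     transcript_median = numeric(),
                     n_max_positions = integer(), stringsAsFactors = FALSE))
  rownames(validated) <- NULL
  summary <- vapply(as.character(0:4),
                    function(k) sum(validated$category == as.integer(k)),
                    integer(1))
  list(validated = validated, summary = summary,
       n_genes = length(unique(validated$transcript_id)),
       n_mirnas = length(unique(validated$mirna_id)))
}
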