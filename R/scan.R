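empty_hits <- function() {
  tibble::tibble(start = integer(0), end = integer(0), score = numeric(0),
                 coverage = numeric(0), match_string = character(0))
}

# encode a protein as 0-based emission-column indices; ambiguity codes map to
# the appended background-expectation column
encode_protein <- function(sequence, n_canonical = 20L) {
  x <- chars(toupper(sequence))
  code <- match(x, aa_alphabet()) - 1L
  unk <- is.na(code)
  if (any(unk)) {
    bad <- unique(x[unk])
    message(sprintf("scored %d non-canonical residue(s) (%s) as background expectation",
                    sum(unk), paste(bad, collapse = ", ")))
    code[unk] <- n_canonical
  }
  code
}

#' Scan a protein for domain occurrences of a scoring profile
#'
#' Runs affine-gap local dynamic programming of the profile columns against
#' the sequence. The best-scoring hit is always reported (when its score is
#' positive); further non-overlapping hits are extracted greedily, best
#' first, while their score stays at or above `score_min`. Non-canonical
#' letters (X, B, Z, U, ...) are scored as the background expectation of the
#' column scores and logged via a message, never fatal.
#'
#' @param profile A [build_profile()] result.
#' @param sequence Protein residue string.
#' @param score_min Bit-score floor for secondary hits (the primary hit is
#'   reported whenever positive).
#' @param max_hits Cap on reported hits per protein.
#' @return A tibble with columns `start`, `end` (1-based inclusive), `score`
#'   (bits), `coverage` (fraction of match columns aligned to a residue) and
#'   `match_string` (length-L string; `-` marks unoccupied match columns).
#' @export
scan_protein <- function(profile, sequence, score_min = 15, max_hits = 5L) {
  stopifnot(inherits(profile, "scoring_profile"), nchar(sequence) >= 1L)
  L <- profile$n_match_columns
  n <- nchar(sequence)
  if (L > 10L * n) {
    warning("profile is more than 10x longer than the sequence; skipping scan")
    return(empty_hits())
  }
  expectation <- as.vector(profile$emissions %*% profile$background)
  emissions <- cbind(profile$emissions, expectation)
  code <- encode_protein(sequence)
  exclude <- rep(FALSE, n)
  seqc <- chars(toupper(sequence))
  hits <- list()
  repeat {
    res <- scan_dp(emissions, code, profile$gap_open, profile$gap_extend,
                   exclude)
    if (is.na(res$start) || res$score <= 0) break
    if (length(hits) >= 1L && res$score < score_min) break
    mp <- res$match_pos
    ms <- rep("-", L)
    ms[mp > 0] <- seqc[mp[mp > 0]]
    hits[[length(hits) + 1L]] <- tibble::tibble(
      start = as.integer(res$start), end = as.integer(res$end),
      score = res$score, coverage = sum(mp > 0) / L,
      match_string = unchars(ms)
    )
    if (length(hits) >= max_hits) break
    exclude[res$start:res$end] <- TRUE
  }
  if (length(hits) == 0L) return(empty_hits())
  dplyr::arrange(dplyr::bind_rows(hits), dplyr::desc(.data$score))
}

#' Scan every protein of a survey table
#'
#' @param profile A [build_profile()] result.
#' @param proteins Tibble with columns `protein_id`, `genome_id`, `group`
#'   (optional) and `sequence`, as produced by [generate_survey()] or
#'   [read_survey_proteins()].
#' @inheritParams scan_protein
#' @return A tibble of hits with `protein_id`, `genome_id`, `group` (when
#'   present), `protein_length` and the [scan_protein()] columns.
#' @export
scan_proteome <- function(profile, proteins, score_min = 15, max_hits = 5L) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  out <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    h <- scan_protein(profile, proteins$sequence[i], score_min = score_min,
                      max_hits = max_hits)
    if (nrow(h) == 0L) next
    meta <- proteins[i, setdiff(names(proteins), "sequence"), drop = FALSE]
    out[[i]] <- dplyr::bind_cols(
      meta[rep(1L, nrow(h)), , drop = FALSE],
      tibble::tibble(protein_length = nchar(proteins$sequence[i])), h
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- dplyr::bind_cols(
      proteins[0, setdiff(names(proteins), "sequence"), drop = FALSE],
      tibble::tibble(protein_length = integer(0)), empty_hits()
    )
  }
  res
}

#' Keep only complete domain hits
#'
#' Operationalizes the "full domain" completeness filter: a hit survives when
#' its match-column coverage and bit score both reach their thresholds. A
#' protein is domain-positive iff at least one hit survives.
#'
#' @param hits A hit tibble from [scan_protein()] or [scan_proteome()].
#' @param coverage_min Minimum coverage (default 0.8).
#' @param score_min Minimum bit score (default 15).
#' @return The filtered tibble.
#' @export
filter_complete <- function(hits, coverage_min = 0.8, score_min = 15) {
  stopifnot(coverage_min >= 0, coverage_min <= 1)
  dplyr::filter(hits, .data$coverage >= coverage_min, .data$score >= score_min)
}
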