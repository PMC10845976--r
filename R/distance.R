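# named character vector of match strings -> character matrix (seq x column)
match_string_matrix <- function(match_strings) {
  stopifnot(!is.null(names(match_strings)),
            length(unique(nchar(match_strings))) == 1L)
  m <- do.call(rbind, strsplit(match_strings, "", fixed = TRUE))
  rownames(m) <- names(match_strings)
  m
}

#' Pairwise distances between match-state strings
#'
#' Match strings share the profile's column coordinate system, so they form
#' an implicit alignment. Each pair is compared over columns where both hold
#' a residue; `p` is the mismatch proportion over those shared columns and
#' the Poisson-corrected distance is `-ln(1 - p)`, capped at `max_distance`.
#' Pairs sharing fewer than `min_shared` columns are flagged with a warning;
#' a pair with zero shared columns is an error (or the cap, under
#' `on_zero_shared = "max"`, used during bootstrap resampling).
#'
#' @param match_strings Named character vector of equal-length match strings
#'   (`-` for unoccupied columns).
#' @param correction `"poisson"` (default) or `"p"` for the raw p-distance.
#' @param max_distance Cap for the Poisson distance (default 5).
#' @param min_shared Minimum shared columns before a pair is flagged.
#' @param on_zero_shared `"error"` or `"max"`.
#' @return A symmetric numeric matrix with zero diagonal and the ids as
#'   dimnames.
#' @export
pairwise_distance <- function(match_strings, correction = c("poisson", "p"),
                              max_distance = 5, min_shared = 20L,
                              on_zero_shared = c("error", "max")) {
  correction <- match.arg(correction)
  on_zero_shared <- match.arg(on_zero_shared)
  m <- match_string_matrix(match_strings)
  n <- nrow(m)
  occ <- (m != "-") * 1L
  shared <- tcrossprod(occ)
  matches <- matrix(0L, n, n)
  for (a in aa_alphabet()) {
    ind <- (m == a) * 1L
    matches <- matches + tcrossprod(ind)
  }
  if (any(shared[upper.tri(shared)] == 0L)) {
    idx <- which(upper.tri(shared) & shared == 0L, arr.ind = TRUE)
    pairs <- paste(rownames(m)[idx[, 1]], rownames(m)[idx[, 2]], sep = " / ")
    if (on_zero_shared == "error")
      stop(sprintf("no shared occupied columns for pair(s): %s",
                   paste(utils::head(pairs, 5L), collapse = "; ")),
           call. = FALSE)
  }
  low <- upper.tri(shared) & shared > 0L & shared < min_shared
  if (any(low)) {
    idx <- which(low, arr.ind = TRUE)
    warning(sprintf("%d pair(s) share fewer than %d columns (e.g. %s / %s)",
                    sum(low), min_shared, rownames(m)[idx[1, 1]],
                    rownames(m)[idx[1, 2]]))
  }
  p <- ifelse(shared > 0L, 1 - matches / pmax(shared, 1L), NA_real_)
  d <- if (correction == "p") {
    ifelse(is.na(p), max_distance, p)
  } else {
    ifelse(is.na(p) | p >= 1 - exp(-max_distance), max_distance, -log(1 - p))
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}
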