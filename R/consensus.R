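#' Per-column residue frequencies and occupancy of match strings
#'
#' Frequencies are computed over residues only — gaps are excluded from the
#' denominator (the WebLogo convention) — with the fraction of members
#' holding a residue reported separately as occupancy. A column with zero
#' residues gets an `NA` frequency row and occupancy 0.
#'
#' @param match_strings Character vector of equal-length match strings.
#' @return A list with `freq` (L x 20 matrix, columns in [aa_alphabet()]
#'   order), `occupancy` (length-L) and `n` (number of strings).
#' @export
column_frequencies <- function(match_strings) {
  stopifnot(length(match_strings) >= 1L,
            length(unique(nchar(match_strings))) == 1L)
  m <- do.call(rbind, strsplit(match_strings, "", fixed = TRUE))
  aa <- aa_alphabet()
  L <- ncol(m)
  occ_n <- colSums(m != "-")
  freq <- matrix(NA_real_, L, 20, dimnames = list(NULL, aa))
  counts <- vapply(aa, function(a) colSums(m == a), numeric(L))
  counts <- matrix(counts, nrow = L, dimnames = list(NULL, aa))
  nz <- occ_n > 0
  freq[nz, ] <- counts[nz, , drop = FALSE] / occ_n[nz]
  list(freq = freq, occupancy = occ_n / nrow(m), n = nrow(m))
}

#' Information content of a frequency row
#'
#' `ic = log2(20) - H(freq)` in bits, the logo stack height. With the
#' small-sample correction on, `e_n = 19 / (2 ln(2) n)` is subtracted and
#' the result floored at zero.
#'
#' @param freq_row Numeric vector of residue frequencies (sums to 1; `NA`
#'   rows give 0).
#' @param n_residues Number of residues behind the row (needed for the
#'   correction).
#' @param small_sample_correction Logical, default `FALSE`.
#' @return Information content in bits, in `[0, log2(20)]`.
#' @export
information_content <- function(freq_row, n_residues = NULL,
                                small_sample_correction = FALSE) {
  if (all(is.na(freq_row))) return(0)
  f <- freq_row[!is.na(freq_row) & freq_row > 0]
  h <- -sum(f * log2(f))
  ic <- log2(20) - h
  if (small_sample_correction) {
    if (is.null(n_residues)) stop("n_residues required for the correction",
                                  call. = FALSE)
    ic <- ic - 19 / (2 * log(2) * n_residues)
  }
  min(max(ic, 0), log2(20))
}

#' Build a consensus logo for one clade
#'
#' Bundles per-column frequencies, occupancy, information content and the
#' consensus residue (modal residue, ties broken alphabetically, `x` where
#' occupancy falls below `min_occupancy`).
#'
#' @param match_strings Character vector of the clade's match strings.
#' @param clade_name Clade label.
#' @param small_sample_correction Passed to [information_content()].
#' @param min_occupancy Occupancy below which the consensus is `x`.
#' @return An object of class `"consensus_logo"`.
#' @export
consensus_logo <- function(match_strings, clade_name = "clade",
                           small_sample_correction = FALSE,
                           min_occupancy = 0.5) {
  cf <- column_frequencies(match_strings)
  L <- nrow(cf$freq)
  ic <- vapply(seq_len(L), function(j) {
    information_content(cf$freq[j, ],
                        n_residues = round(cf$occupancy[j] * cf$n),
                        small_sample_correction = small_sample_correction)
  }, numeric(1))
  logo <- structure(
    list(clade_name = clade_name, L = L, freq = cf$freq,
         occupancy = cf$occupancy, ic = ic, n = cf$n,
         consensus = NA_character_),
    class = "consensus_logo"
  )
  logo$consensus <- consensus_sequence(logo, min_occupancy = min_occupancy)
  logo
}

#' Consensus sequence of a logo
#'
#' Per column the modal residue (the top of the logo stack); ties broken
#' alphabetically; `x` when occupancy is below `min_occupancy`.
#'
#' @param logo A [consensus_logo()].
#' @param min_occupancy Occupancy threshold, default 0.5.
#' @return A length-L residue string over the 20 letters plus `x`.
#' @export
consensus_sequence <- function(logo, min_occupancy = 0.5) {
  stopifnot(inherits(logo, "consensus_logo"))
  aa <- aa_alphabet()
  out <- vapply(seq_len(logo$L), function(j) {
    if (is.na(logo$occupancy[j]) || logo$occupancy[j] < min_occupancy ||
        all(is.na(logo$freq[j, ]))) return("x")
    aa[which.max(logo$freq[j, ])]
  }, "")
  unchars(out)
}

#' @export
print.consensus_logo <- function(x, ...) {
  cat(sprintf("consensus_logo '%s': %d columns over %d sequences\n",
              x$clade_name, x$L, x$n))
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

#' Call cross-clade conserved and consensus-dominant sites
#'
#' A position is conserved when every clade reaches both the information
#' content and occupancy thresholds there; it is additionally dominant when
#' all clades agree on one modal residue. Dominant positions are always a
#' subset of conserved positions.
#'
#' @param logos List of [consensus_logo()] objects with a common L.
#' @param ic_min Minimum per-clade information content (bits), default 2.
#' @param occupancy_min Minimum per-clade occupancy, default 0.5.
#' @return A list with `positions` (conserved column indices),
#'   `dominant_positions`, and `modal` (L x n_clades matrix of modal
#'   residues).
#' @export
call_conserved_sites <- function(logos, ic_min = 2, occupancy_min = 0.5) {
  stopifnot(length(logos) >= 2L)
  Ls <- vapply(logos, function(l) l$L, integer(1))
  if (length(unique(Ls)) != 1L)
    stop("all logos must share the same number of columns", call. = FALSE)
  L <- Ls[1]
  aa <- aa_alphabet()
  modal <- vapply(logos, function(l) {
    vapply(seq_len(L), function(j) {
      if (all(is.na(l$freq[j, ]))) NA_character_ else aa[which.max(l$freq[j, ])]
    }, "")
  }, character(L))
  modal <- matrix(modal, nrow = L,
                  dimnames = list(NULL, vapply(logos, function(l)
                    l$clade_name, "")))
  ok_ic <- matrix(vapply(logos, function(l) l$ic >= ic_min, logical(L)),
                  nrow = L)
  ok_occ <- matrix(vapply(logos, function(l) l$occupancy >= occupancy_min,
                          logical(L)), nrow = L)
  conserved <- which(apply(ok_ic & ok_occ, 1L, all))
  dominant <- conserved[vapply(conserved, function(j) {
    r <- modal[j, ]
    !anyNA(r) && length(unique(r)) == 1L
  }, TRUE)]
  list(positions = conserved, dominant_positions = dominant, modal = modal)
}

#' Segment the profile into characteristic motif blocks
#'
#' Finds maximal runs of conserved columns separated by gaps longer than
#' `run_break` and reports the three longest (in profile order) as motifs
#' 1–3. Conservation is judged on a pooled logo built from all clades'
#' match strings combined — cross-clade information content is high only
#' inside blocks conserved across the whole family, which is what separates
#' the motif blocks from the unconserved linker. A logical conservation
#' vector may be passed directly instead.
#'
#' @param x A pooled [consensus_logo()], or a logical vector marking
#'   conserved columns.
#' @param ic_min,occupancy_min Thresholds applied when `x` is a logo.
#' @param run_break Maximum gap (columns) bridged within one run; default 3.
#' @return A tibble with columns `motif`, `start`, `end`, `length`
#'   (possibly fewer than three rows, with a warning).
#' @export
motif_segments <- function(x, ic_min = 2, occupancy_min = 0.5,
                           run_break = 3L) {
  conserved <- if (inherits(x, "consensus_logo")) {
    x$ic >= ic_min & x$occupancy >= occupancy_min
  } else {
    as.logical(x)
  }
  idx <- which(conserved)
  empty <- tibble::tibble(motif = character(0), start = integer(0),
                          end = integer(0), length = integer(0))
  if (length(idx) == 0L) {
    warning("no conserved columns; no motifs detected")
    return(empty)
  }
  brk <- c(0L, which(diff(idx) > run_break + 1L), length(idx))
  runs <- lapply(seq_len(length(brk) - 1L), function(k) {
    idx[(brk[k] + 1L):brk[k + 1L]]
  })
  if (length(runs) < 3L)
    warning(sprintf("only %d conserved run(s) found; expected 3 motifs",
                    length(runs)))
  if (length(runs) > 3L) {
    warning(sprintf("%d conserved runs found; keeping the 3 longest",
                    length(runs)))
    keep <- order(-lengths(runs))[1:3]
    runs <- runs[sort(keep)]
  }
  tibble::tibble(
    motif = paste0("motif", seq_along(runs)),
    start = vapply(runs, min, integer(1)),
    end = vapply(runs, max, integer(1)),
    length = vapply(runs, function(r) max(r) - min(r) + 1L, integer(1))
  )
}

#' Tabulate a consensus logo (for TSV export)
#'
#' @param logo A [consensus_logo()].
#' @return A tibble: `clade`, `column`, the 20 residue frequencies,
#'   `occupancy`, `ic`, `consensus`, `chemistry`.
#' @export
logo_table <- function(logo) {
  stopifnot(inherits(logo, "consensus_logo"))
  cons <- chars(logo$consensus)
  dplyr::bind_cols(
    tibble::tibble(clade = logo$clade_name, column = seq_len(logo$L)),
    tibble::as_tibble(logo$freq),
    tibble::tibble(occupancy = logo$occupancy, ic = logo$ic,
                   consensus = cons, chemistry = residue_chemistry(cons))
  )
}
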