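#' Seed alignment container
#'
#' A multiple alignment of the target domain: equal-length rows over the 20
#' canonical letters plus `-` for gaps, with unique sequence ids.
#'
#' @param ids Character vector of unique sequence ids.
#' @param rows Character vector of equal-length aligned residue strings.
#' @return An object of class `"seed_alignment"`.
#' @export
seed_alignment <- function(ids, rows) {
  stopifnot(length(ids) == length(rows))
  if (length(rows) < 2L) stop("a seed alignment needs at least 2 rows", call. = FALSE)
  if (anyDuplicated(ids)) stop("seed alignment ids must be unique", call. = FALSE)
  w <- unique(nchar(rows))
  if (length(w) != 1L || w < 1L)
    stop("all alignment rows must have the same positive length", call. = FALSE)
  ok <- c(aa_alphabet(), "-")
  for (i in seq_along(rows)) {
    bad <- setdiff(unique(chars(rows[i])), ok)
    if (length(bad) > 0L)
      stop(sprintf("row %s contains invalid characters: %s", ids[i],
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(ids = ids, rows = rows, width = w), class = "seed_alignment")
}

#' Read an aligned FASTA file as a seed alignment
#'
#' @param path Aligned FASTA file (gaps as `-`).
#' @return A [seed_alignment()].
#' @export
read_seed_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seed_alignment(ids = names(ss), rows = as.character(ss))
}

# alignment rows as a character matrix (rows x columns)
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

#' Determine match columns of a seed alignment
#'
#' A column is a match column when the fraction of rows holding a residue
#' (not a gap) is at least `occupancy_threshold`, the usual occupancy rule
#' for profile construction.
#'
#' @param alignment A [seed_alignment()].
#' @param occupancy_threshold Fraction in `(0, 1]`; default 0.5.
#' @return Logical vector, one entry per alignment column.
#' @export
determine_match_columns <- function(alignment, occupancy_threshold = 0.5) {
  stopifnot(inherits(alignment, "seed_alignment"),
            occupancy_threshold > 0, occupancy_threshold <= 1)
  m <- alignment_matrix(alignment)
  occ <- colMeans(m != "-")
  mask <- occ >= occupancy_threshold
  if (!any(mask))
    stop("degenerate alignment: no column reaches the occupancy threshold",
         call. = FALSE)
  mask
}

#' Build a position-specific log-odds scoring profile
#'
#' For match column `c` and residue `a` the emission score in bits is
#' `log2((n_ca + alpha * bg_a) / (N_c + alpha) / bg_a)`, with counts taken
#' over non-gap rows of the column. With `pseudocount = 0`, residues unseen
#' in a column receive a large negative sentinel (-1000) in place of
#' negative infinity.
#'
#' @param alignment A [seed_alignment()].
#' @param mask Logical match-column mask; computed by
#'   [determine_match_columns()] when `NULL`.
#' @param pseudocount Pseudocount mass `alpha >= 0`; default 1.
#' @param background Length-20 background probabilities (order of
#'   [aa_alphabet()]); default uniform.
#' @param gap_open,gap_extend Affine gap scores in bits (both `<= 0`,
#'   `gap_open <= gap_extend`).
#' @param occupancy_threshold Used when `mask` is `NULL`.
#' @return An object of class `"scoring_profile"`: `emissions` (L x 20 bits),
#'   `background`, `gap_open`, `gap_extend`, `match_column_map`, `consensus`.
#' @export
build_profile <- function(alignment, mask = NULL, pseudocount = 1,
                          background = rep(1 / 20, 20),
                          gap_open = -4, gap_extend = -0.5,
                          occupancy_threshold = 0.5) {
  stopifnot(inherits(alignment, "seed_alignment"), pseudocount >= 0,
            length(background) == 20, all(background > 0))
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1", call. = FALSE)
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("gap scores must satisfy gap_open <= gap_extend <= 0", call. = FALSE)
  if (is.null(mask)) mask <- determine_match_columns(alignment, occupancy_threshold)
  stopifnot(length(mask) == alignment$width)
  m <- alignment_matrix(alignment)[, mask, drop = FALSE]
  aa <- aa_alphabet()
  L <- ncol(m)
  emissions <- matrix(NA_real_, L, 20, dimnames = list(NULL, aa))
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col != "-"]
    n <- table(factor(col, levels = aa))
    p <- (as.numeric(n) + pseudocount * background) /
      (length(col) + pseudocount)
    e <- log2(p / background)
    e[!is.finite(e)] <- -1000
    emissions[j, ] <- e
  }
  structure(
    list(n_match_columns = L, emissions = emissions,
         background = background, gap_open = gap_open,
         gap_extend = gap_extend, match_column_map = which(mask),
         consensus = unchars(aa[apply(emissions, 1L, which.max)])),
    class = "scoring_profile"
  )
}

#' @export
print.scoring_profile <- function(x, ...) {
  cat(sprintf("scoring_profile: %d match columns, gap open %.2f / extend %.2f bits\n",
              x$n_match_columns, x$gap_open, x$gap_extend))
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

#' Serialize a scoring profile (TSV emissions + JSON header)
#'
#' Writes `<prefix>.tsv` (one row per match column: index and the 20 scores)
#' and `<prefix>.json` (background, gap scores, match-column map).
#'
#' @param profile A [build_profile()] result.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_profile <- function(profile, prefix) {
  stopifnot(inherits(profile, "scoring_profile"))
  tab <- data.frame(column = seq_len(profile$n_match_columns),
                    profile$emissions, check.names = FALSE)
  utils::write.table(tab, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(background = profile$background, gap_open = profile$gap_open,
         gap_extend = profile$gap_extend,
         match_column_map = profile$match_column_map,
         consensus = profile$consensus),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' Read a scoring profile written by [write_profile()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `"scoring_profile"` object.
#' @export
read_profile <- function(prefix) {
  tab <- utils::read.delim(paste0(prefix, ".tsv"), check.names = FALSE)
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  emissions <- as.matrix(tab[, aa_alphabet()])
  dimnames(emissions) <- list(NULL, aa_alphabet())
  structure(
    list(n_match_columns = nrow(emissions), emissions = emissions,
         background = hdr$background, gap_open = hdr$gap_open,
         gap_extend = hdr$gap_extend,
         match_column_map = hdr$match_column_map, consensus = hdr$consensus),
    class = "scoring_profile"
  )
}
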