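#' Domain template: three conserved motif blocks and a variable linker
#'
#' A velvet-like domain is modelled as three conserved motif blocks — by
#' default exactly 33, 44 and 36 residues — separated by an unconserved
#' linker of variable length between motifs 1 and 2 and a short spacer
#' between motifs 2 and 3. The template fixes the motif residue content
#' (drawn once from the uniform amino-acid background when not supplied)
#' and the admissible linker/spacer length ranges.
#'
#' @param motif1,motif2,motif3 Residue strings for the three motif blocks.
#'   When `NULL`, random strings of lengths 33/44/36 are drawn
#'   deterministically from `rng_seed`.
#' @param linker_length_range Integer pair `(min, max)` of linker lengths
#'   (residues) between motif 1 and motif 2.
#' @param spacer_length_range Integer pair `(min, max)` of spacer lengths
#'   between motif 2 and motif 3.
#' @param rng_seed Integer seed governing motif drawing and the random
#'   linker/spacer content in [make_root_domain()].
#' @return An object of class `"domain_template"`.
#' @export
domain_template <- function(motif1 = NULL, motif2 = NULL, motif3 = NULL,
                            linker_length_range = c(20L, 40L),
                            spacer_length_range = c(6L, 12L),
                            rng_seed = 1L) {
  stopifnot(length(linker_length_range) == 2L, length(spacer_length_range) == 2L)
  linker_length_range <- as.integer(linker_length_range)
  spacer_length_range <- as.integer(spacer_length_range)
  if (linker_length_range[1] < 0L || linker_length_range[1] > linker_length_range[2])
    stop("linker_length_range must satisfy 0 <= min <= max", call. = FALSE)
  if (spacer_length_range[1] < 0L || spacer_length_range[1] > spacer_length_range[2])
    stop("spacer_length_range must satisfy 0 <= min <= max", call. = FALSE)
  if (is.null(motif1) || is.null(motif2) || is.null(motif3)) {
    drawn <- withr::with_seed(mix_seed(rng_seed, 1L), lapply(c(33L, 44L, 36L), function(n) {
      unchars(sample(aa_alphabet(), n, replace = TRUE))
    }))
    if (is.null(motif1)) motif1 <- drawn[[1]]
    if (is.null(motif2)) motif2 <- drawn[[2]]
    if (is.null(motif3)) motif3 <- drawn[[3]]
  }
  check_canonical(motif1, "motif1")
  check_canonical(motif2, "motif2")
  check_canonical(motif3, "motif3")
  structure(
    list(motif1 = motif1, motif2 = motif2, motif3 = motif3,
         linker_length_range = linker_length_range,
         spacer_length_range = spacer_length_range,
         rng_seed = as.integer(rng_seed)),
    class = "domain_template"
  )
}

#' Build the ancestral (root) domain sequence from a template
#'
#' Concatenates motif 1, a random linker, motif 2, a random short spacer and
#' motif 3. Linker and spacer lengths are drawn uniformly from the template
#' ranges and their residues from the uniform background. Deterministic given
#' the template's `rng_seed`.
#'
#' @param template A [domain_template()].
#' @return A residue string with attributes `motif_mask` (logical per
#'   position, `TRUE` on motif blocks) and `motif_cols` (a list of the three
#'   1-based motif column ranges).
#' @export
make_root_domain <- function(template) {
  stopifnot(inherits(template, "domain_template"))
  withr::with_seed(mix_seed(template$rng_seed, 2L), {
    lr <- template$linker_length_range
    sr <- template$spacer_length_range
    linker_len <- if (lr[1] == lr[2]) lr[1] else sample(lr[1]:lr[2], 1L)
    spacer_len <- if (sr[1] == sr[2]) sr[1] else sample(sr[1]:sr[2], 1L)
    linker <- unchars(sample(aa_alphabet(), linker_len, replace = TRUE))
    spacer <- unchars(sample(aa_alphabet(), spacer_len, replace = TRUE))
    n1 <- nchar(template$motif1); n2 <- nchar(template$motif2); n3 <- nchar(template$motif3)
    seqc <- paste0(template$motif1, linker, template$motif2, spacer, template$motif3)
    m1 <- c(1L, n1)
    m2 <- c(n1 + linker_len + 1L, n1 + linker_len + n2)
    m3 <- c(m2[2] + spacer_len + 1L, m2[2] + spacer_len + n3)
    mask <- rep(FALSE, nchar(seqc))
    mask[m1[1]:m1[2]] <- TRUE
    mask[m2[1]:m2[2]] <- TRUE
    mask[m3[1]:m3[2]] <- TRUE
    structure(seqc, motif_mask = mask,
              motif_cols = list(motif1 = m1, motif2 = m2, motif3 = m3))
  })
}

#' Evolve a sequence by per-site substitution and linker-restricted indels
#'
#' Each position substitutes independently with probability `rate`; positions
#' flagged in `motif_mask` substitute at `rate / 4`, emulating motif
#' conservation, and positions flagged in `invariant` never change.
#' Substitutions are drawn uniformly from the 19 alternative residues.
#' Insertions/deletions of single residues occur only at non-motif (linker and
#' spacer) positions, at `indel_rate` per site, so motif blocks keep their
#' length and the implicit match-state coordinate system stays well-posed.
#'
#' @param parent Residue string.
#' @param rate Substitution probability per site, in `[0, 1)`... `1` is
#'   accepted as the forced-substitution limit.
#' @param seed Integer seed; the operation is deterministic given it.
#' @param motif_mask Logical vector, length of `parent`; `NULL` means no
#'   masking (all sites at full rate, indels everywhere).
#' @param indel_rate Per-site indel probability on unmasked positions.
#' @param invariant Optional logical vector marking absolutely conserved
#'   positions (substitution and indel rate 0).
#' @return The evolved residue string, with attributes `motif_mask` and
#'   `invariant` remapped to the child coordinates, and `match_string`: the
#'   child written in the parent's coordinate system (deleted positions as
#'   `-`, inserted residues omitted) — the true match-state alignment.
#' @export
evolve_sequence <- function(parent, rate, seed, motif_mask = NULL,
                            indel_rate = 0.01, invariant = NULL) {
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    stop("rate must lie in [0, 1]", call. = FALSE)
  check_canonical(parent, "parent")
  x <- chars(parent)
  n <- length(x)
  if (is.null(motif_mask)) motif_mask <- rep(FALSE, n)
  if (is.null(invariant)) invariant <- rep(FALSE, n)
  stopifnot(length(motif_mask) == n, length(invariant) == n)
  aa <- aa_alphabet()
  withr::with_seed(mix_seed(seed, 4L), {
    p <- ifelse(motif_mask, rate / 4, rate)
    p[invariant] <- 0
    hit <- stats::runif(n) < p
    if (any(hit)) {
      x[hit] <- vapply(x[hit], function(r) sample(setdiff(aa, r), 1L), "")
    }
    aligned <- x  # child in parent coordinates; deletions marked below
    # indels: single-residue, restricted to unmasked (linker/flank) positions
    if (indel_rate > 0) {
      free <- which(!motif_mask & !invariant)
      if (length(free) > 0L) {
        ev <- free[stats::runif(length(free)) < indel_rate]
        if (length(ev) > 0L) {
          is_del <- stats::runif(length(ev)) < 0.5
          del_at <- ev[is_del]
          ins_at <- ev[!is_del]
          ins_res <- sample(aa, length(ins_at), replace = TRUE)
          keep <- rep(TRUE, n)
          keep[del_at] <- FALSE
          aligned[del_at] <- "-"
          pieces <- vector("list", n)
          for (i in seq_len(n)) {
            pieces[[i]] <- if (keep[i]) list(x[i], motif_mask[i], invariant[i]) else NULL
          }
          # insertions placed after their anchor position
          for (k in seq_along(ins_at)) {
            i <- ins_at[k]
            anchor <- pieces[[i]]
            pieces[[i]] <- if (is.null(anchor)) {
              list(ins_res[k], FALSE, FALSE)
            } else {
              list(c(anchor[[1]], ins_res[k]), c(anchor[[2]], FALSE),
                   c(anchor[[3]], FALSE))
            }
          }
          pieces <- pieces[!vapply(pieces, is.null, TRUE)]
          x <- unlist(lapply(pieces, `[[`, 1L))
          motif_mask <- unlist(lapply(pieces, `[[`, 2L))
          invariant <- unlist(lapply(pieces, `[[`, 3L))
        }
      }
    }
  })
  structure(unchars(x), motif_mask = motif_mask, invariant = invariant,
            match_string = unchars(aligned))
}
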