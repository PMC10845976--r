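#' The 20 canonical amino-acid letters
#'
#' Returned in alphabetical order; this ordering is used throughout the
#' package for emission matrices, frequency tables and alphabetical
#' tie-breaking of consensus residues.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# letters treated as ambiguity/non-canonical codes during scanning
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O", "J", "*")

#' Chemical class of a residue
#'
#' The five-way classification used for logo colouring: polar (G, S, T, Y, C),
#' neutral (Q, N), basic (K, R, H), acidic (D, E) and hydrophobic
#' (A, V, L, I, P, W, F, M).
#'
#' @param residue Character vector of single residue letters; `"x"` or `"-"`
#'   yield `NA`.
#' @return Character vector of class labels.
#' @export
residue_chemistry <- function(residue) {
  cls <- c(
    G = "polar", S = "polar", T = "polar", Y = "polar", C = "polar",
    Q = "neutral", N = "neutral",
    K = "basic", R = "basic", H = "basic",
    D = "acidic", E = "acidic",
    A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
    I = "hydrophobic", P = "hydrophobic", W = "hydrophobic",
    F = "hydrophobic", M = "hydrophobic"
  )
  unname(cls[toupper(residue)])
}

# derive a decorrelated RNG seed for a named stream; prevents distinct
# simulation stages seeded with the same small integer from sharing draws
mix_seed <- function(seed, salt) {
  x <- (abs(as.double(seed)) %% 2147483646) + 1
  for (s in c(salt, 40503)) x <- (x * 48271 + s) %% 2147483647
  as.integer(x)
}

# split a residue string into a character vector
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# collapse a character vector back into a string
unchars <- function(x) paste(x, collapse = "")

# validate that a string uses only the canonical alphabet
check_canonical <- function(x, what = "sequence") {
  bad <- setdiff(unique(chars(x)), aa_alphabet())
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-canonical letters: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Rand index between two clusterings
#'
#' Proportion of element pairs on which two partitions agree (both together or
#' both apart). Used to score recovery of planted clade memberships.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A number in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) return(1)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
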