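#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (Saitou–Nei): at each step the pair minimizing
#' `Q(i, j) = (n - 2) d(i, j) - r_i - r_j` is joined, with the standard
#' branch-length formulas and distance reduction. Q ties are broken toward
#' the smallest index pair in the current working order (original input
#' order, merged clusters taking the smaller of the two merged slots), which
#' makes the construction deterministic. A negative branch length is clamped
#' to zero and its deficit moved to the sister edge so the joined pair keeps
#' its total length. Zero-distance (duplicate) taxa are aggregated into
#' zero-length cherries before the Q iterations — plain NJ can otherwise
#' leave such a pair unresolved in the final trifurcation.
#'
#' @param dm Symmetric numeric distance matrix with ids as dimnames (zero
#'   diagonal, `n >= 3`).
#' @return An unrooted `phylo` tree (root trifurcation), leaf labels taken
#'   from the matrix dimnames.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L)
    stop("trivial tree: neighbor joining needs at least 3 taxa", call. = FALSE)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  if (max(abs(dm - t(dm))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  D <- (dm + t(dm)) / 2
  lab <- rownames(D)
  # pre-aggregate duplicates (zero off-diagonal distance)
  repeat {
    if (n <= 3L) break
    Z <- D <= 1e-15
    diag(Z) <- FALSE
    Z[lower.tri(Z)] <- FALSE
    if (!any(Z)) break
    idx <- which(Z, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    newlab <- sprintf("(%s:0,%s:0)", lab[i], lab[j])
    keep <- setdiff(seq_len(n), c(i, j))
    dnew <- (D[i, keep] + D[j, keep]) / 2
    ord <- order(c(keep, i))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew),
               c(dnew, 0))[ord, ord]
    lab <- c(lab[keep], newlab)[ord]
    n <- n - 1L
  }
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(vi + vj, 0); vj <- 0 }
    newlab <- sprintf("(%s:%.10g,%s:%.10g)", lab[i], vi, lab[j], vj)
    dnew <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- matrix(0, n - 1L, n - 1L)
    D2[seq_len(n - 2L), seq_len(n - 2L)] <- D[keep, keep]
    D2[n - 1L, seq_len(n - 2L)] <- dnew
    D2[seq_len(n - 2L), n - 1L] <- dnew
    # reinsert the merged cluster at the smaller of the two merged slots to
    # keep the tie-break order stable
    ord <- order(c(keep, i))
    D <- D2[ord, ord]
    lab <- c(lab[keep], newlab)[ord]
    n <- n - 1L
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    lab[1], v[1], lab[2], v[2], lab[3], v[3])
  ape::read.tree(text = newick)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples match columns with replacement, rebuilds the distance matrix and
#' NJ tree per replicate, and reports for each internal edge of the
#' point-estimate tree the percentage of replicates containing the same
#' bipartition. Deterministic given `seed`. Replicates in which a pair loses
#' all shared columns fall back to the distance cap rather than failing.
#'
#' @param match_strings Named character vector of equal-length match strings.
#' @param n_replicates Number of bootstrap replicates (`>= 1`).
#' @param seed Integer seed.
#' @inheritParams pairwise_distance
#' @return A list with `tree` (the point-estimate `phylo`, `node.label` set
#'   to integer percent support) and `support` (numeric vector per internal
#'   node).
#' @export
bootstrap_support <- function(match_strings, n_replicates = 100L, seed = 1L,
                              correction = "poisson", max_distance = 5,
                              min_shared = 20L) {
  stopifnot(n_replicates >= 1L)
  m <- match_string_matrix(match_strings)
  L <- ncol(m)
  point <- nj_tree(pairwise_distance(match_strings, correction = correction,
                                     max_distance = max_distance,
                                     min_shared = min_shared))
  boot <- withr::with_seed(mix_seed(seed, 7L), lapply(seq_len(n_replicates), function(b) {
    cols <- sample.int(L, L, replace = TRUE)
    ms <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    suppressWarnings(nj_tree(pairwise_distance(
      ms, correction = correction, max_distance = max_distance,
      min_shared = min_shared, on_zero_shared = "max")))
  }))
  class(boot) <- "multiPhylo"
  counts <- ape::prop.clades(point, part = ape::prop.part(boot),
                             rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_replicates)
  point$node.label <- as.character(support)
  list(tree = point, support = support)
}
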