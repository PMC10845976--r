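# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the aligner oracle enumerates alignments by recursion,
# the tree oracle enumerates topologies and fits branch lengths by least
# squares.

# exhaustive enumeration of gapped local alignments (affine gaps); an
# alignment starts and ends with a profile column aligned to a residue
brute_local_score <- function(emissions, seq_codes, gap_open, gap_extend) {
  L <- nrow(emissions)
  n <- length(seq_codes)
  best <- 0
  rec <- function(i, j, state, score) {
    if (state == "M" && score > best) best <<- score
    if (i < L && j < n)
      rec(i + 1L, j + 1L, "M",
          score + emissions[i + 1L, seq_codes[j + 1L] + 1L])
    if (j < n)
      rec(i, j + 1L, "Ix",
          score + if (state == "Ix") gap_extend else gap_open)
    if (i < L)
      rec(i + 1L, j, "Iy",
          score + if (state == "Iy") gap_extend else gap_open)
  }
  for (i0 in seq_len(L)) {
    for (j0 in seq_len(n)) {
      rec(i0, j0, "M", emissions[i0, seq_codes[j0] + 1L])
    }
  }
  unname(best)
}

# sum of squared residuals of the OLS branch-length fit of a topology to a
# distance matrix
ls_topology_sse <- function(tree, d) {
  tips <- tree$tip.label
  n <- length(tips)
  E <- nrow(tree$edge)
  pairs <- utils::combn(n, 2L)
  A <- matrix(0, ncol(pairs), E)
  b <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; bb <- pairs[2, k]
    path <- ape::nodepath(tree, a, bb)
    for (s in seq_len(length(path) - 1L)) {
      e <- which((tree$edge[, 1] == path[s] & tree$edge[, 2] == path[s + 1]) |
                   (tree$edge[, 2] == path[s] & tree$edge[, 1] == path[s + 1]))
      A[k, e] <- 1
    }
    b[k] <- d[tips[a], tips[bb]]
  }
  fit <- stats::lm.fit(A, b)
  sum(fit$residuals^2)
}

# best topology for a distance matrix by exhaustive enumeration (n <= 6)
ls_best_topology <- function(d) {
  labels <- rownames(d)
  stopifnot(length(labels) <= 6L)
  trees <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  sse <- vapply(trees, ls_topology_sse, numeric(1), d = d)
  trees[[which.min(sse)]]
}

# random unrooted binary tree with positive branch lengths and its additive
# (path-length) distance matrix
random_additive_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.2, 1.5))
    d <- ape::cophenetic.phylo(tr)
    list(tree = tr, d = d[order(rownames(d)), order(colnames(d))])
  })
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# manual type-7 quantile (linear interpolation), independent of quantile()
type7_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
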