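#' Box-plot summary of a numeric vector
#'
#' Quartiles use linear interpolation (type 7); whiskers extend to the most
#' extreme data points within the Tukey fences (1.5 IQR beyond the
#' quartiles); notches are `median +/- 1.58 IQR / sqrt(n)`.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return A list of class `"box_summary"`: `n`, `mean`, `median`, `q1`,
#'   `q3`, `iqr`, `whisker_low`, `whisker_high`, `notch_low`, `notch_high`,
#'   `outliers`.
#' @export
box_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("box_summary needs at least one value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(
    list(n = n, mean = mean(values), median = q[2], q1 = q[1], q3 = q[3],
         iqr = iqr,
         whisker_low = min(values[inside]),
         whisker_high = max(values[inside]),
         notch_low = q[2] - 1.58 * iqr / sqrt(n),
         notch_high = q[2] + 1.58 * iqr / sqrt(n),
         outliers = sort(values[!inside])),
    class = "box_summary"
  )
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(
    "box_summary: n=%d mean=%.4g median=%.4g [q1=%.4g, q3=%.4g] whiskers [%.4g, %.4g] outliers=%d\n",
    x$n, x$mean, x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
    length(x$outliers)))
  invisible(x)
}

#' Unpaired two-group t-test with the survey's significance conventions
#'
#' Pooled-variance Student t by default (`df = n_a + n_b - 2`), Welch via
#' `welch = TRUE`. P below 0.05 is flagged significant, below 0.001 highly
#' significant. Two equal constant groups give `t = 0, p = 1`; zero pooled
#' variance with unequal means is reported as `p = 0` and flagged degenerate.
#'
#' @param a,b Numeric vectors, each `n >= 2`.
#' @param welch Use the Welch (unequal-variance) variant.
#' @return A list of class `"ttest_result"`: `t`, `df`, `p`, `significant`,
#'   `highly_significant`, `degenerate`.
#' @export
two_group_ttest <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  degenerate <- FALSE
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      t <- 0; p <- 1; df <- length(a) + length(b) - 2
    } else {
      t <- sign(mean(a) - mean(b)) * Inf; p <- 0
      df <- length(a) + length(b) - 2
      degenerate <- TRUE
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch)
    t <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  structure(
    list(t = t, df = df, p = p,
         significant = p < 0.05, highly_significant = p < 0.001,
         degenerate = degenerate),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.4g, p = %.4g%s%s\n", x$t, x$df, x$p,
              if (x$highly_significant) " (highly significant)"
              else if (x$significant) " (significant)" else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' All pairwise two-group t-tests across clades
#'
#' Raw two-sided p-values per pair as in the survey's clade length
#' comparisons; a Bonferroni-adjusted column is added for transparency but
#' the significance flags follow the raw values.
#'
#' @param values_by_group Named list of numeric vectors (e.g. protein
#'   lengths per clade).
#' @param welch Passed to [two_group_ttest()].
#' @return A tibble with one row per unordered pair: `group1`, `group2`,
#'   `n1`, `n2`, `mean1`, `mean2`, `t`, `df`, `p`, `p_bonferroni`,
#'   `significant`, `highly_significant`.
#' @export
pairwise_ttests <- function(values_by_group, welch = FALSE) {
  nm <- names(values_by_group)
  stopifnot(!is.null(nm), length(nm) >= 2L)
  pairs <- utils::combn(nm, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    tt <- two_group_ttest(values_by_group[[g1]], values_by_group[[g2]],
                          welch = welch)
    tibble::tibble(group1 = g1, group2 = g2,
                   n1 = length(values_by_group[[g1]]),
                   n2 = length(values_by_group[[g2]]),
                   mean1 = mean(values_by_group[[g1]]),
                   mean2 = mean(values_by_group[[g2]]),
                   t = tt$t, df = tt$df, p = tt$p,
                   significant = tt$significant,
                   highly_significant = tt$highly_significant)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out[, c("group1", "group2", "n1", "n2", "mean1", "mean2", "t", "df", "p",
          "p_bonferroni", "significant", "highly_significant")]
}
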