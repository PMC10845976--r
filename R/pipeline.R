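#' Best match string per protein
#'
#' Keeps, for every protein in a hit table, the match string of its
#' top-scoring hit; the result is the input to distance and consensus
#' computations.
#'
#' @param hits Hit tibble from [scan_proteome()] (filtered or not).
#' @return Named character vector of match strings.
#' @export
best_match_strings <- function(hits) {
  stopifnot(all(c("protein_id", "score", "match_string") %in% names(hits)))
  h <- dplyr::slice_max(dplyr::group_by(hits, .data$protein_id),
                        order_by = .data$score, n = 1L, with_ties = FALSE)
  stats::setNames(h$match_string, h$protein_id)
}

# match string of the single best hit of one sequence (references, outgroup)
single_match_string <- function(profile, sequence) {
  h <- scan_protein(profile, sequence, score_min = 0)
  if (nrow(h) == 0L) stop("sequence yields no profile hit", call. = FALSE)
  h$match_string[1]
}

#' Reference-anchored clade classification of a synthetic survey
#'
#' Runs the classification stage end to end: profile match strings for the
#' surviving domain proteins, the four reference anchors (the planted clade
#' ancestors, standing in for the VeA/VelB/VelC/VosA references) and the
#' outgroup; Poisson-corrected distances; a neighbor-joining tree (with
#' bootstrap support when `n_bootstrap > 0`); rooting on the outgroup and
#' reference-anchored clade assignment with group-aware names.
#'
#' @param survey A [generate_survey()] result.
#' @param profile A [build_profile()] result.
#' @param hits Optional pre-computed filtered hit table; scanned and
#'   filtered at default thresholds when `NULL`.
#' @param n_bootstrap Bootstrap replicates (0 disables support values).
#' @param seed Seed for the bootstrap resampling.
#' @param support_threshold Passed to [assign_clades()].
#' @param coverage_min,score_min Completeness thresholds used when `hits` is
#'   `NULL`.
#' @return A list with `tree`, `assignments` (named clade tibble), `hits`,
#'   and `match_strings`.
#' @export
survey_clades <- function(survey, profile, hits = NULL, n_bootstrap = 0L,
                          seed = 1L, support_threshold = 50,
                          coverage_min = 0.8, score_min = 15) {
  stopifnot(inherits(survey, "velvet_survey"))
  if (is.null(hits)) {
    hits <- filter_complete(scan_proteome(profile, survey$proteins),
                            coverage_min = coverage_min,
                            score_min = score_min)
  }
  ms <- best_match_strings(hits)
  fam <- survey$family
  n_ref <- min(4L, length(fam$ancestors))
  anchors <- c("VeA", "VelB", "VelC", "VosA")[seq_len(n_ref)]
  ref_ids <- paste0("ref_", anchors)
  ref_ms <- vapply(fam$ancestors[seq_len(n_ref)], function(s)
    single_match_string(profile, s), "", USE.NAMES = FALSE)
  all_ms <- c(ms, stats::setNames(ref_ms, ref_ids),
              outgroup = single_match_string(profile, fam$outgroup))
  if (n_bootstrap > 0L) {
    bs <- bootstrap_support(all_ms, n_replicates = n_bootstrap, seed = seed)
    tree <- bs$tree
  } else {
    tree <- nj_tree(pairwise_distance(all_ms))
  }
  assignments <- assign_clades(tree, stats::setNames(anchors, ref_ids),
                               "outgroup",
                               support_threshold = support_threshold)
  group_of <- stats::setNames(survey$proteins$group, survey$proteins$protein_id)
  assignments <- name_clades(assignments, group_of)
  list(tree = tree, assignments = assignments, hits = hits,
       match_strings = all_ms)
}

#' Per-clade consensus logos from assigned match strings
#'
#' @param match_strings Named character vector (ids matching the clade
#'   memberships).
#' @param clade_members Named list: clade name -> member ids.
#' @param ... Passed to [consensus_logo()].
#' @return Named list of [consensus_logo()] objects.
#' @export
clade_logos <- function(match_strings, clade_members, ...) {
  stopifnot(length(clade_members) >= 1L, !is.null(names(clade_members)))
  out <- lapply(names(clade_members), function(nm) {
    ids <- intersect(clade_members[[nm]], names(match_strings))
    if (length(ids) == 0L)
      stop(sprintf("clade %s has no match strings", nm), call. = FALSE)
    consensus_logo(match_strings[ids], clade_name = nm, ...)
  })
  stats::setNames(out, names(clade_members))
}

#' Neighbor-joining tree over per-clade consensus sequences
#'
#' Consensus strings share the profile coordinate system, so they are
#' compared directly; low-occupancy columns (`x`) are treated as gaps.
#'
#' @param logos Named list of [consensus_logo()] objects.
#' @param correction Passed to [pairwise_distance()].
#' @return A `phylo` tree with one leaf per clade.
#' @export
clade_consensus_tree <- function(logos, correction = "poisson") {
  cons <- vapply(logos, function(l) gsub("x", "-", l$consensus, fixed = TRUE),
                 "")
  nj_tree(pairwise_distance(cons, correction = correction))
}
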