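#' Classify the position of a domain within its protein
#'
#' The midpoint fraction is `((start + end) / 2) / protein_length`. A domain
#' whose midpoint lies before 40% of the protein is N-terminal-side, after
#' 60% C-terminal-side, otherwise middle; both boundaries are strict, so a
#' fraction of exactly 0.40 or 0.60 is middle.
#'
#' @param start,end 1-based inclusive domain coordinates (vectorized).
#' @param protein_length Protein length in residues (vectorized).
#' @return A tibble with `midpoint_fraction` and `label` (`"N"`, `"middle"`,
#'   `"C"`).
#' @export
classify_position <- function(start, end, protein_length) {
  if (any(start < 1L) || any(end < start))
    stop("invalid domain coordinates: need 1 <= start <= end", call. = FALSE)
  if (any(protein_length < end))
    stop("coordinate error: domain end exceeds protein length", call. = FALSE)
  frac <- ((start + end) / 2) / protein_length
  label <- ifelse(frac < 0.40, "N", ifelse(frac > 0.60, "C", "middle"))
  tibble::tibble(midpoint_fraction = frac, label = label)
}

#' Per-genome summaries of surviving domain hits
#'
#' One row per manifest genome, including genomes without any hit
#' (`velvet_count = 0`). Protein and domain lengths are recorded per hit;
#' the domain length of a filtered hit is `end - start + 1`.
#'
#' @param hits Filtered hit tibble from [scan_proteome()] +
#'   [filter_complete()]; needs `genome_id`, `protein_length`, `start`,
#'   `end`.
#' @param manifest Tibble with `genome_id` and `group` covering every genome.
#' @return A tibble with `genome_id`, `group`, `velvet_count` and list
#'   columns `protein_lengths`, `domain_lengths`, `position_labels`.
#' @export
summarize_genomes <- function(hits, manifest) {
  stopifnot(all(c("genome_id", "group") %in% names(manifest)))
  unknown <- setdiff(unique(hits$genome_id), manifest$genome_id)
  if (length(unknown) > 0L)
    stop(sprintf("hits reference genomes absent from the manifest: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  pos <- if (nrow(hits) > 0L) {
    classify_position(hits$start, hits$end, hits$protein_length)$label
  } else character(0)
  tibble::tibble(
    genome_id = manifest$genome_id,
    group = manifest$group,
    velvet_count = vapply(manifest$genome_id, function(g)
      sum(hits$genome_id == g), integer(1), USE.NAMES = FALSE),
    protein_lengths = lapply(manifest$genome_id, function(g)
      hits$protein_length[hits$genome_id == g]),
    domain_lengths = lapply(manifest$genome_id, function(g)
      (hits$end - hits$start + 1L)[hits$genome_id == g]),
    position_labels = lapply(manifest$genome_id, function(g)
      pos[hits$genome_id == g])
  )
}

# smallest modal value of an integer vector, with tie flag
count_mode <- function(x) {
  if (length(x) == 0L) return(list(mode = NA_integer_, tied = FALSE))
  tab <- table(x)
  modal <- as.integer(names(tab)[tab == max(tab)])
  list(mode = min(modal), tied = length(modal) > 1L)
}

#' Per-group survey statistics
#'
#' Mirrors the headline survey panels: percentage of genomes carrying at
#' least one domain gene, the per-genome count mode among domain-positive
#' genomes (zero-count genomes excluded from the mode and histogram but
#' included in the percentage), mean protein and domain lengths, and the
#' percentage of N-side / middle / C-side domain positions.
#'
#' Mode ties are broken toward the smaller count and flagged.
#'
#' @param summaries Output of [summarize_genomes()].
#' @return A tibble with one row per group: `group`, `n_genomes`,
#'   `percent_with_genes`, `count_mode`, `count_mode_tied`, `count_histogram`
#'   (list column of named counts), `mean_protein_len`, `mean_domain_len`,
#'   `pct_N`, `pct_middle`, `pct_C`.
#' @export
group_statistics <- function(summaries) {
  groups <- unique(summaries$group)
  rows <- lapply(groups, function(g) {
    s <- summaries[summaries$group == g, ]
    positive <- s$velvet_count > 0L
    md <- count_mode(s$velvet_count[positive])
    labs <- unlist(s$position_labels)
    npos <- length(labs)
    tibble::tibble(
      group = g,
      n_genomes = nrow(s),
      percent_with_genes = 100 * mean(positive),
      count_mode = md$mode,
      count_mode_tied = md$tied,
      count_histogram = list(table(s$velvet_count[positive])),
      mean_protein_len = mean(unlist(s$protein_lengths)),
      mean_domain_len = mean(unlist(s$domain_lengths)),
      pct_N = if (npos) 100 * sum(labs == "N") / npos else NA_real_,
      pct_middle = if (npos) 100 * sum(labs == "middle") / npos else NA_real_,
      pct_C = if (npos) 100 * sum(labs == "C") / npos else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}
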