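write_tsv_det <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  basename(path)
}

#' Write the consolidated survey report bundle
#'
#' Emits machine-readable TSV tables for whichever components are supplied —
#' per-group survey statistics, the clade table, pairwise clade length
#' comparisons, conserved-site calls, clan membership, per-clade logos and
#' the rejected-protein log — plus an `index.json` listing the files written
#' together with run metadata (seed, parameters, package version). Rerunning
#' with identical inputs reproduces byte-identical tables.
#'
#' @param out_dir Output directory (created if absent).
#' @param survey_stats Optional [group_statistics()] tibble.
#' @param clades Optional [name_clades()] tibble.
#' @param clade_tests Optional [pairwise_ttests()] tibble.
#' @param conserved Optional [call_conserved_sites()] result.
#' @param clans Optional [clan_partition()] result.
#' @param logos Optional list of [consensus_logo()] objects.
#' @param rejected Optional tibble of proteins rejected by the completeness
#'   filter (decoy log).
#' @param run_info Named list of run metadata (seed, parameters, ...).
#' @return Invisibly, the list of files written.
#' @export
render_report <- function(out_dir, survey_stats = NULL, clades = NULL,
                          clade_tests = NULL, conserved = NULL, clans = NULL,
                          logos = NULL, rejected = NULL, run_info = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (!is.null(survey_stats)) {
    tab <- dplyr::select(survey_stats, -dplyr::any_of("count_histogram"))
    files <- c(files, write_tsv_det(tab, file.path(out_dir, "group_stats.tsv")))
  }
  if (!is.null(clades)) {
    flat <- tidyr::unnest(
      dplyr::select(clades, dplyr::any_of(c("clade_name", "anchor",
                                            "member_ids"))),
      "member_ids")
    names(flat)[names(flat) == "member_ids"] <- "protein_id"
    flat <- flat[order(flat$clade_name, flat$protein_id), ]
    files <- c(files, write_tsv_det(flat, file.path(out_dir, "clades.tsv")))
  } else {
    files <- c(files, write_tsv_det(
      tibble::tibble(clade_name = character(0), anchor = character(0),
                     protein_id = character(0)),
      file.path(out_dir, "clades.tsv")))
  }
  if (!is.null(clade_tests)) {
    files <- c(files, write_tsv_det(
      clade_tests, file.path(out_dir, "clade_length_tests.tsv")))
  }
  if (!is.null(conserved)) {
    tab <- tibble::tibble(
      position = conserved$positions,
      dominant = conserved$positions %in% conserved$dominant_positions
    )
    tab <- dplyr::bind_cols(
      tab, tibble::as_tibble(conserved$modal[conserved$positions, ,
                                             drop = FALSE]))
    files <- c(files, write_tsv_det(
      tab, file.path(out_dir, "conserved_sites.tsv")))
  }
  if (!is.null(clans)) {
    tab <- tibble::tibble(
      clan = rep(names(clans), lengths(clans)),
      leaf = unlist(clans, use.names = FALSE)
    )
    files <- c(files, write_tsv_det(tab, file.path(out_dir, "clans.tsv")))
  }
  if (!is.null(logos)) {
    tab <- dplyr::bind_rows(lapply(logos, logo_table))
    files <- c(files, write_tsv_det(tab, file.path(out_dir, "logos.tsv")))
  }
  if (!is.null(rejected)) {
    files <- c(files, write_tsv_det(
      rejected, file.path(out_dir, "rejected_proteins.tsv")))
  }
  jsonlite::write_json(
    list(files = sort(files),
         package = "velvetsurvey",
         version = as.character(utils::packageVersion("velvetsurvey")),
         run_info = run_info),
    file.path(out_dir, "index.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(files, "index.json"))
}

#' Write per-clade consensus sequences as FASTA
#'
#' @param logos List of [consensus_logo()] objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(logos, path) {
  seqs <- vapply(logos, function(l) l$consensus, "")
  # 'x' marks columns below the occupancy floor; X is its FASTA counterpart
  ss <- Biostrings::AAStringSet(gsub("x", "X", seqs, fixed = TRUE))
  names(ss) <- vapply(logos, function(l) l$clade_name, "")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
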