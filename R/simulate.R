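#' Simulate a multi-clade domain family with known ground truth
#'
#' Descends a root domain (from [make_root_domain()]) into `n_clades` clade
#' ancestors and then into clade members. Motif positions substitute at a
#' quarter of the nominal rate; a planted set of `n_invariant` motif positions
#' never changes in any lineage (the "kingdom-invariant" sites that
#' cross-clade conserved-residue calling should recover). Linker indels act
#' only on members, so all ancestors share the root coordinate system. With
#' `n_clans = 2` the root first splits into two diverged clan ancestors and
#' clades alternate between them, emulating the deep two-clan structure of
#' the velvet family.
#'
#' @param template A [domain_template()].
#' @param n_clades Number of clades.
#' @param members_per_clade Members simulated per clade.
#' @param between_clade_divergence Substitution rate root (or clan ancestor)
#'   to clade ancestor, per site.
#' @param within_clade_divergence Substitution rate clade ancestor to member.
#' @param indel_rate Per-site linker indel rate on members.
#' @param n_invariant Number of absolutely conserved motif positions.
#' @param n_clans 1 or 2 deep clans.
#' @param clan_divergence Substitution rate root to clan ancestor (used when
#'   `n_clans = 2`).
#' @param outgroup_divergence Substitution rate root to the outgroup sequence
#'   (masked like any lineage, so the outgroup still carries a recognizable
#'   domain while sitting far outside the clade radiation).
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return A list of class `"velvet_family"`: `root`, `motif_mask`,
#'   `motif_cols`, `invariant_sites` (root coordinates), `clan_of_clade`,
#'   `ancestors` (character vector), `outgroup`, and `members`, a tibble with
#'   columns `id`, `clade`, `clan`, `sequence` and `match_string` — the
#'   member's true alignment in root (match-state) coordinates, part of the
#'   generator's ground truth.
#' @export
simulate_family <- function(template = domain_template(),
                            n_clades = 4L,
                            members_per_clade = 50L,
                            between_clade_divergence = 0.3,
                            within_clade_divergence = 0.05,
                            indel_rate = 0.01,
                            n_invariant = 48L,
                            n_clans = 1L,
                            clan_divergence = 0.5,
                            outgroup_divergence = 0.6,
                            seed = 1L) {
  stopifnot(n_clades >= 1L, members_per_clade >= 1L, n_clans %in% c(1L, 2L))
  if (between_clade_divergence < 0 || between_clade_divergence >= 1 ||
      within_clade_divergence < 0 || within_clade_divergence >= 1)
    stop("divergences must lie in [0, 1)", call. = FALSE)
  root <- make_root_domain(template)
  mask <- attr(root, "motif_mask")
  motif_cols <- attr(root, "motif_cols")
  n_invariant <- min(n_invariant, sum(mask))
  withr::with_seed(mix_seed(seed, 3L), {
    inv_sites <- sort(sample(which(mask), n_invariant))
    invariant <- rep(FALSE, nchar(root))
    invariant[inv_sites] <- TRUE
    sub_seeds <- sample.int(.Machine$integer.max - 1L,
                            1L + n_clans + n_clades + n_clades * members_per_clade)
  })
  outgroup <- as.character(evolve_sequence(root, outgroup_divergence,
                                           sub_seeds[1], motif_mask = mask,
                                           indel_rate = 0,
                                           invariant = invariant))
  k <- 1L
  clan_anc <- character(n_clans)
  if (n_clans == 2L) {
    for (cl in 1:2) {
      k <- k + 1L
      clan_anc[cl] <- evolve_sequence(root, clan_divergence, sub_seeds[k],
                                      motif_mask = mask, indel_rate = 0,
                                      invariant = invariant)
    }
  } else {
    clan_anc[1] <- as.character(root)
    k <- k + n_clans
  }
  clan_of_clade <- if (n_clans == 2L) rep_len(1:2, n_clades) else rep(1L, n_clades)
  ancestors <- character(n_clades)
  for (cl in seq_len(n_clades)) {
    k <- k + 1L
    ancestors[cl] <- evolve_sequence(clan_anc[clan_of_clade[cl]],
                                     between_clade_divergence, sub_seeds[k],
                                     motif_mask = mask, indel_rate = 0,
                                     invariant = invariant)
  }
  ids <- character(0); clades <- integer(0); seqs <- character(0)
  truems <- character(0)
  for (cl in seq_len(n_clades)) {
    for (m in seq_len(members_per_clade)) {
      k <- k + 1L
      s <- evolve_sequence(ancestors[cl], within_clade_divergence, sub_seeds[k],
                           motif_mask = mask, indel_rate = indel_rate,
                           invariant = invariant)
      ids <- c(ids, sprintf("c%02dm%03d", cl, m))
      clades <- c(clades, cl)
      seqs <- c(seqs, as.character(s))
      truems <- c(truems, attr(s, "match_string"))
    }
  }
  structure(
    list(root = as.character(root), motif_mask = mask, motif_cols = motif_cols,
         invariant_sites = inv_sites, clan_of_clade = clan_of_clade,
         clan_ancestors = clan_anc, ancestors = ancestors, outgroup = outgroup,
         members = tibble::tibble(id = ids, clade = clades,
                                  clan = clan_of_clade[clades],
                                  sequence = seqs, match_string = truems)),
    class = "velvet_family"
  )
}

#' Simulate a seed alignment for profile construction
#'
#' Generates `n_rows` indel-free descendants of the root domain at the given
#' divergence (motif positions at a quarter rate). Because no indels are
#' applied, the rows are mutually aligned by construction and every column is
#' occupied; the alignment serves as the in-repo stand-in for a curated
#' domain seed alignment.
#'
#' @inheritParams simulate_family
#' @param n_rows Number of alignment rows.
#' @param divergence Per-site substitution rate from the root.
#' @return A [seed_alignment()].
#' @export
simulate_seed_alignment <- function(template = domain_template(),
                                    n_rows = 12L, divergence = 0.3, seed = 1L) {
  root <- make_root_domain(template)
  mask <- attr(root, "motif_mask")
  seeds <- withr::with_seed(mix_seed(seed, 5L), sample.int(.Machine$integer.max - 1L, n_rows))
  rows <- vapply(seq_len(n_rows), function(i) {
    as.character(evolve_sequence(root, divergence, seeds[i],
                                 motif_mask = mask, indel_rate = 0))
  }, "")
  seed_alignment(ids = sprintf("seed%02d", seq_len(n_rows)), rows = rows)
}

#' Survey configuration
#'
#' Bundles the parameters of a synthetic kingdom survey: taxonomic groups,
#' genomes per group, the per-genome gene-count distribution, clade structure
#' and divergences, flank-length ranges realizing each domain-position class,
#' and the decoy rate. Defaults emulate a small five-group survey with a
#' per-genome count mode of 4 (the Pezizomycotina mode) and roughly one decoy
#' per ten domain proteins.
#'
#' @param groups Character vector of taxonomic group names.
#' @param genomes_per_group Genomes simulated per group.
#' @param gene_count_distribution Named numeric vector: names are gene counts,
#'   values probabilities summing to 1.
#' @param n_clades,between_clade_divergence,within_clade_divergence,indel_rate,n_invariant,n_clans,clan_divergence
#'   Passed to [simulate_family()].
#' @param position_class_probs Named probabilities for classes `N`, `middle`,
#'   `C`.
#' @param flank_length_ranges Named list (`N`, `middle`, `C`), each a list
#'   with integer pairs `left` and `right` giving flank-length ranges.
#' @param decoys_per_genome Expected decoy proteins per genome (fractional
#'   part realized as a Bernoulli draw).
#' @param template A [domain_template()].
#' @param seed Integer seed.
#' @return A list of class `"survey_config"`.
#' @export
survey_config <- function(groups = c("Pezizomycotina", "Saccharomycotina",
                                     "Agaricomycotina", "Mucoromycotina",
                                     "Blastocladiomycota"),
                          genomes_per_group = 10L,
                          gene_count_distribution = c("3" = 0.2, "4" = 0.6, "5" = 0.2),
                          n_clades = 4L,
                          between_clade_divergence = 0.3,
                          within_clade_divergence = 0.05,
                          indel_rate = 0.01,
                          n_invariant = 48L,
                          n_clans = 1L,
                          clan_divergence = 0.5,
                          position_class_probs = c(N = 0.5, middle = 0.3, C = 0.2),
                          flank_length_ranges = list(
                            N = list(left = c(0L, 40L), right = c(200L, 400L)),
                            middle = list(left = c(60L, 160L), right = c(60L, 160L)),
                            C = list(left = c(200L, 400L), right = c(0L, 40L))
                          ),
                          decoys_per_genome = 0.4,
                          template = domain_template(),
                          seed = 1L) {
  if (abs(sum(gene_count_distribution) - 1) > 1e-9)
    stop("gene_count_distribution probabilities must sum to 1", call. = FALSE)
  if (any(gene_count_distribution < 0))
    stop("gene_count_distribution probabilities must be non-negative", call. = FALSE)
  if (is.null(names(gene_count_distribution)))
    stop("gene_count_distribution must be named by gene count", call. = FALSE)
  stopifnot(setequal(names(position_class_probs), c("N", "middle", "C")),
            abs(sum(position_class_probs) - 1) < 1e-9,
            setequal(names(flank_length_ranges), c("N", "middle", "C")),
            decoys_per_genome >= 0)
  for (cls in names(flank_length_ranges)) {
    fr <- flank_length_ranges[[cls]]
    if (any(unlist(fr) < 0))
      stop(sprintf("flank ranges for class %s must be non-negative", cls),
           call. = FALSE)
  }
  structure(
    list(groups = groups, genomes_per_group = as.integer(genomes_per_group),
         gene_count_distribution = gene_count_distribution,
         n_clades = as.integer(n_clades),
         between_clade_divergence = between_clade_divergence,
         within_clade_divergence = within_clade_divergence,
         indel_rate = indel_rate, n_invariant = as.integer(n_invariant),
         n_clans = as.integer(n_clans), clan_divergence = clan_divergence,
         position_class_probs = position_class_probs[c("N", "middle", "C")],
         flank_length_ranges = flank_length_ranges,
         decoys_per_genome = decoys_per_genome,
         template = template, seed = as.integer(seed)),
    class = "survey_config"
  )
}

# uniform draw from an integer range, safe for degenerate ranges
sample_range <- function(a, b) if (a == b) a else sample(a:b, 1L)

# draw flank lengths realizing a position class by rejection sampling
draw_flanks <- function(cls, dom_len, ranges, max_attempts = 1000L) {
  lr <- ranges[[cls]]$left; rr <- ranges[[cls]]$right
  for (i in seq_len(max_attempts)) {
    left <- sample_range(lr[1], lr[2])
    right <- sample_range(rr[1], rr[2])
    start <- left + 1L
    end <- left + dom_len
    frac <- ((start + end) / 2) / (left + dom_len + right)
    lab <- if (frac < 0.40) "N" else if (frac > 0.60) "C" else "middle"
    if (lab == cls) return(c(left = left, right = right))
  }
  stop(sprintf(
    "flank ranges for position class '%s' cannot realize that class (domain length %d)",
    cls, dom_len), call. = FALSE)
}

#' Generate a synthetic proteome survey with ground truth
#'
#' For each genome a gene count is drawn from the configured distribution;
#' each gene is a clade member domain (clades assigned uniformly) embedded
#' between random flanks whose lengths realize a drawn domain-position class
#' under the midpoint rule (rejection sampling, at most 1000 attempts).
#' Composition-shuffled decoy proteins carry no domain. The returned truth
#' table records, per protein, the planted clade, 1-based inclusive domain
#' coordinates and position class (`clade_index = -1`, coordinates `-1`,
#' class `"none"` for decoys).
#'
#' @param config A [survey_config()].
#' @return A list of class `"velvet_survey"`: `proteins` (tibble: `protein_id`,
#'   `genome_id`, `group`, `sequence`), `truth` (tibble: `protein_id`,
#'   `genome_id`, `group`, `clade_index`, `domain_start`, `domain_end`,
#'   `true_position_class`, `member_id`), `manifest` (tibble: `genome_id`, `group`),
#'   `family` (the underlying [simulate_family()] output) and `config`.
#' @export
generate_survey <- function(config = survey_config()) {
  stopifnot(inherits(config, "survey_config"))
  n_genomes <- length(config$groups) * config$genomes_per_group
  counts <- as.integer(names(config$gene_count_distribution))
  # member pool drawn without replacement across the survey; clade draws are
  # multinomial, so size each clade's pool for the worst case
  need <- n_genomes * max(counts)
  fam <- simulate_family(
    template = config$template, n_clades = config$n_clades,
    members_per_clade = need,
    between_clade_divergence = config$between_clade_divergence,
    within_clade_divergence = config$within_clade_divergence,
    indel_rate = config$indel_rate, n_invariant = config$n_invariant,
    n_clans = config$n_clans, clan_divergence = config$clan_divergence,
    seed = config$seed + 1L
  )
  aa <- aa_alphabet()
  next_member <- rep(1L, config$n_clades)
  withr::with_seed(mix_seed(config$seed, 6L), {
    manifest <- tibble::tibble(
      genome_id = sprintf("g%03d", seq_len(n_genomes)),
      group = rep(config$groups, each = config$genomes_per_group)
    )
    prot <- list(); tru <- list()
    for (gi in seq_len(n_genomes)) {
      gid <- manifest$genome_id[gi]
      grp <- manifest$group[gi]
      n_genes <- if (length(counts) == 1L) counts else
        sample(counts, 1L, prob = config$gene_count_distribution)
      for (j in seq_len(n_genes)) {
        clade <- sample.int(config$n_clades, 1L)
        idx <- which(fam$members$clade == clade)[next_member[clade]]
        if (is.na(idx)) stop("member pool exhausted; internal sizing error")
        next_member[clade] <- next_member[clade] + 1L
        dom <- fam$members$sequence[idx]
        cls <- sample(c("N", "middle", "C"), 1L,
                      prob = config$position_class_probs)
        fl <- draw_flanks(cls, nchar(dom), config$flank_length_ranges)
        left <- unchars(sample(aa, fl["left"], replace = TRUE))
        right <- unchars(sample(aa, fl["right"], replace = TRUE))
        pid <- sprintf("%s_p%02d", gid, j)
        prot[[length(prot) + 1L]] <- tibble::tibble(
          protein_id = pid, genome_id = gid, group = grp,
          sequence = paste0(left, dom, right)
        )
        tru[[length(tru) + 1L]] <- tibble::tibble(
          protein_id = pid, genome_id = gid, group = grp,
          clade_index = clade,
          domain_start = fl[["left"]] + 1L,
          domain_end = fl[["left"]] + nchar(dom),
          true_position_class = cls,
          member_id = fam$members$id[idx]
        )
      }
      # decoys: composition-shuffled copies of a domain protein
      gene_seqs <- if (n_genes > 0L) {
        vapply(prot[seq(length(prot) - n_genes + 1L, length(prot))],
               function(z) z$sequence, "")
      } else {
        paste0(unchars(sample(aa, 150L, replace = TRUE)), fam$root)
      }
      n_dec <- floor(config$decoys_per_genome) +
        (stats::runif(1) < (config$decoys_per_genome %% 1))
      for (d in seq_len(n_dec)) {
        src <- gene_seqs[1L + (d - 1L) %% length(gene_seqs)]
        dec <- unchars(sample(chars(src)))
        pid <- sprintf("%s_d%02d", gid, d)
        prot[[length(prot) + 1L]] <- tibble::tibble(
          protein_id = pid, genome_id = gid, group = grp, sequence = dec
        )
        tru[[length(tru) + 1L]] <- tibble::tibble(
          protein_id = pid, genome_id = gid, group = grp,
          clade_index = -1L, domain_start = -1L, domain_end = -1L,
          true_position_class = "none", member_id = NA_character_
        )
      }
    }
  })
  structure(
    list(proteins = dplyr::bind_rows(prot), truth = dplyr::bind_rows(tru),
         manifest = manifest, family = fam, config = config),
    class = "velvet_survey"
  )
}

#' Write a survey to disk (FASTA per genome, manifest and truth TSV)
#'
#' @param survey A [generate_survey()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "velvet_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gid in survey$manifest$genome_id) {
    p <- survey$proteins[survey$proteins$genome_id == gid, ]
    ss <- Biostrings::AAStringSet(p$sequence)
    names(ss) <- paste(p$protein_id, p$genome_id)
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(gid, ".fasta")))
  }
  utils::write.table(survey$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(survey$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read proteomes written by [write_survey()] back into a protein table
#'
#' @param dir Directory holding `*.fasta` files and `manifest.tsv`.
#' @return A tibble with columns `protein_id`, `genome_id`, `group`,
#'   `sequence`.
#' @export
read_survey_proteins <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  out <- lapply(manifest$genome_id, function(gid) {
    ss <- Biostrings::readAAStringSet(file.path(dir, paste0(gid, ".fasta")))
    ids <- vapply(strsplit(names(ss), " ", fixed = TRUE), `[[`, "", 1L)
    tibble::tibble(protein_id = ids, genome_id = gid,
                   group = manifest$group[manifest$genome_id == gid],
                   sequence = unname(as.character(ss)))
  })
  dplyr::bind_rows(out)
}
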