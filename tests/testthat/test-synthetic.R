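test_that("root domain concatenates motifs with linker and spacer", {
  # degenerate ranges: no inserted residues at all
  t0 <- domain_template(linker_length_range = c(0, 0),
                        spacer_length_range = c(0, 0), rng_seed = 3)
  root <- make_root_domain(t0)
  root_s <- as.character(root)
  expect_equal(nchar(root_s), 33 + 44 + 36)
  expect_equal(substr(root_s, 1, 33), t0$motif1)
  expect_equal(substr(root_s, 34, 77), t0$motif2)
  expect_equal(substr(root_s, 78, 113), t0$motif3)
  mc <- attr(root, "motif_cols")
  expect_equal(mc$motif1, c(1L, 33L))
  expect_equal(mc$motif3, c(78L, 113L))

  # determinism: same template gives byte-identical roots
  t1 <- domain_template(rng_seed = 42)
  expect_identical(as.character(make_root_domain(t1)),
                   as.character(make_root_domain(t1)))

  # invalid alphabet rejected
  expect_error(domain_template(motif1 = "ACDEX1"), "non-canonical")
})

test_that("linker lengths are uniform over their range", {
  lens <- vapply(1:1000, function(s) {
    tpl <- domain_template(linker_length_range = c(20, 60),
                           spacer_length_range = c(0, 0), rng_seed = s)
    nchar(make_root_domain(tpl)) - 113L
  }, integer(1))
  expect_true(all(lens >= 20 & lens <= 60))
  se <- sd(20:60) / sqrt(1000)
  expect_lt(abs(mean(lens) - 40), 3 * se)
})

test_that("evolve_sequence respects rate, mask and determinism", {
  parent <- random_aa(200, seed = 10)
  expect_identical(as.character(evolve_sequence(parent, 0, seed = 1,
                                                indel_rate = 0)), parent)

  # forced substitution: every position changes
  child <- evolve_sequence(parent, 1, seed = 2, indel_rate = 0)
  expect_equal(sum(strsplit(parent, "")[[1]] ==
                     strsplit(child, "")[[1]]), 0)

  expect_identical(as.character(evolve_sequence(parent, 0.3, seed = 5)),
                   as.character(evolve_sequence(parent, 0.3, seed = 5)))
  expect_error(evolve_sequence(parent, 1.2, seed = 1), "rate")

  # binomial expectation: unmasked substitutions at rate 0.1 over 500 reps
  nsub <- vapply(1:500, function(s) {
    ch <- evolve_sequence(parent, 0.1, seed = s, indel_rate = 0)
    sum(strsplit(parent, "")[[1]] != strsplit(ch, "")[[1]])
  }, numeric(1))
  se <- sqrt(200 * 0.1 * 0.9) / sqrt(500)
  expect_lt(abs(mean(nsub) - 20), 3 * se)
})

test_that("indels stay out of motif blocks and the true alignment is exact", {
  tpl <- tiny_template()
  root <- make_root_domain(tpl)
  mask <- attr(root, "motif_mask")
  for (s in 1:30) {
    ch <- evolve_sequence(root, 0.1, seed = s, motif_mask = mask,
                          indel_rate = 0.2)
    new_mask <- attr(ch, "motif_mask")
    # motif blocks keep their length through indels
    expect_equal(sum(new_mask), sum(mask))
    aligned <- attr(ch, "match_string")
    expect_equal(nchar(aligned), nchar(root))
    # removing deletions from the alignment leaves a subsequence of the child
    kept <- strsplit(gsub("-", "", aligned), "")[[1]]
    childc <- strsplit(as.character(ch), "")[[1]]
    j <- 1
    for (r in kept) {
      while (j <= length(childc) && childc[j] != r) j <- j + 1
      expect_lte(j, length(childc))
      j <- j + 1
    }
  }
})

test_that("survey counting, self-consistency and determinism hold", {
  cfg <- survey_config(groups = "Pezizomycotina", genomes_per_group = 5L,
                       gene_count_distribution = c("3" = 1),
                       decoys_per_genome = 0, seed = 4)
  s <- generate_survey(cfg)
  expect_equal(nrow(s$truth), 15L)
  expect_true(all(s$truth$clade_index >= 1))

  # planted domain is recovered exactly from the truth coordinates
  merged <- merge(s$truth, s$proteins, by = "protein_id")
  dom <- substr(merged$sequence, merged$domain_start, merged$domain_end)
  fam_seq <- setNames(s$family$members$sequence, s$family$members$id)
  expect_identical(dom, unname(fam_seq[merged$member_id]))

  # recomputing the midpoint class from truth coordinates reproduces it
  lens <- nchar(merged$sequence)
  lab <- classify_position(merged$domain_start, merged$domain_end, lens)$label
  expect_identical(lab, merged$true_position_class)

  # byte-identical regeneration
  s2 <- generate_survey(cfg)
  expect_identical(s$proteins, s2$proteins)
  expect_identical(s$truth, s2$truth)
})

test_that("within-clade distances are below between-clade distances", {
  fam <- simulate_family(n_clades = 4, members_per_clade = 8,
                         between_clade_divergence = 0.3,
                         within_clade_divergence = 0.05, seed = 6)
  ms <- setNames(fam$members$match_string, fam$members$id)
  d <- pairwise_distance(ms, correction = "p")
  same <- outer(fam$members$clade, fam$members$clade, "==")
  ut <- upper.tri(d)
  expect_lt(mean(d[ut & same]), mean(d[ut & !same]))
  # indeed every between-pair exceeds every within-pair mean comfortably
  expect_lt(max(d[ut & same]), min(d[ut & !same]))
})

test_that("survey writes and reads back identically", {
  cfg <- survey_config(groups = c("Pezizomycotina", "Mucoromycotina"),
                       genomes_per_group = 2L, decoys_per_genome = 1,
                       seed = 8)
  s <- generate_survey(cfg)
  dir <- withr::local_tempdir()
  write_survey(s, dir)
  back <- read_survey_proteins(dir)
  expect_identical(back$sequence, s$proteins$sequence)
  expect_identical(back$protein_id, s$proteins$protein_id)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), nrow(s$truth))
})

test_that("impossible flank ranges fail naming the class", {
  cfg <- survey_config(
    flank_length_ranges = list(
      N = list(left = c(300L, 400L), right = c(0L, 5L)),
      middle = list(left = c(60L, 160L), right = c(60L, 160L)),
      C = list(left = c(200L, 400L), right = c(0L, 40L))
    ),
    position_class_probs = c(N = 1, middle = 0, C = 0),
    genomes_per_group = 1L, groups = "Pezizomycotina", seed = 1)
  expect_error(generate_survey(cfg), "'N'")
})
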