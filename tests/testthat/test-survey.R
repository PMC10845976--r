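test_that("midpoint position rule matches its definition and boundaries", {
  # the VeA-like span 34-231 in a 573-residue protein sits N-terminal
  pc <- classify_position(34L, 231L, 573L)
  expect_equal(pc$midpoint_fraction, 132.5 / 573, tolerance = 1e-12)
  expect_identical(pc$label, "N")

  # exact 40% boundary is middle (strict inequality)
  pc2 <- classify_position(30L, 50L, 100L)
  expect_equal(pc2$midpoint_fraction, 0.40)
  expect_identical(pc2$label, "middle")
  # exact 60% boundary is middle too
  pc3 <- classify_position(50L, 70L, 100L)
  expect_equal(pc3$midpoint_fraction, 0.60)
  expect_identical(pc3$label, "middle")

  pc4 <- classify_position(161L, 200L, 200L)
  expect_equal(pc4$midpoint_fraction, 0.9025)
  expect_identical(pc4$label, "C")

  expect_error(classify_position(10L, 120L, 100L), "coordinate")
})

test_that("position classes agree with an independent recomputation", {
  s <- generate_survey(survey_config(genomes_per_group = 2L, seed = 5))
  pos <- s$truth[s$truth$clade_index > 0, ]
  lens <- nchar(s$proteins$sequence[match(pos$protein_id,
                                          s$proteins$protein_id)])
  got <- classify_position(pos$domain_start, pos$domain_end, lens)$label
  frac <- ((pos$domain_start + pos$domain_end) / 2) / lens
  want <- ifelse(frac < 0.4, "N", ifelse(frac > 0.6, "C", "middle"))
  expect_identical(got, want)
  expect_identical(got, pos$true_position_class)
})

# build a perfect-detection hit table straight from a survey's truth
truth_hits <- function(s) {
  pos <- s$truth[s$truth$clade_index > 0, ]
  tibble::tibble(
    protein_id = pos$protein_id, genome_id = pos$genome_id,
    group = pos$group,
    protein_length = nchar(s$proteins$sequence[match(pos$protein_id,
                                                     s$proteins$protein_id)]),
    start = pos$domain_start, end = pos$domain_end,
    score = 100, coverage = 1, match_string = "X"
  )
}

test_that("genome summaries cover all genomes and validate input", {
  manifest <- tibble::tibble(genome_id = c("g1", "g2", "g3"),
                             group = "Pezizomycotina")
  hits <- tibble::tibble(genome_id = c("g1", "g1", "g2"),
                         protein_length = c(400L, 300L, 500L),
                         start = c(10L, 10L, 300L), end = c(150L, 150L, 450L))
  sm <- summarize_genomes(hits, manifest)
  expect_equal(sm$velvet_count, c(2L, 1L, 0L))
  gs <- group_statistics(sm)
  expect_equal(gs$percent_with_genes, 100 * 2 / 3, tolerance = 1e-9)

  bad <- dplyr::mutate(hits, genome_id = c("g1", "gX", "g2"))
  expect_error(summarize_genomes(bad, manifest), "gX")
})

test_that("count modes, ties and histograms follow the declared rules", {
  manifest <- tibble::tibble(genome_id = sprintf("g%d", 1:5), group = "Gp")
  counts <- c(4L, 4L, 3L, 4L, 2L)
  hits <- tibble::tibble(
    genome_id = rep(manifest$genome_id, counts),
    protein_length = 300L, start = 10L, end = 150L
  )
  gs <- group_statistics(summarize_genomes(hits, manifest))
  expect_equal(gs$count_mode, 4L)
  expect_false(gs$count_mode_tied)
  expect_equal(sum(gs$count_histogram[[1]]), 5L)  # all genomes positive

  # tie broken toward the smaller count, and flagged
  counts2 <- c(2L, 2L, 3L, 3L, 0L)
  hits2 <- tibble::tibble(
    genome_id = rep(manifest$genome_id, counts2),
    protein_length = 300L, start = 10L, end = 150L
  )
  gs2 <- group_statistics(summarize_genomes(hits2, manifest))
  expect_equal(gs2$count_mode, 2L)
  expect_true(gs2$count_mode_tied)
  # zero-count genome excluded from histogram, included in percentage
  expect_equal(sum(gs2$count_histogram[[1]]), 4L)
  expect_equal(gs2$percent_with_genes, 80)

  # a single genome with two genes
  gs3 <- group_statistics(summarize_genomes(hits2[1:2, ], manifest[1, ]))
  expect_equal(gs3$count_mode, 2L)
  expect_equal(gs3$percent_with_genes, 100)
})

test_that("empirical count mode recovers the sampled distribution", {
  cfg <- survey_config(groups = "Pezizomycotina", genomes_per_group = 200L,
                       gene_count_distribution = c("3" = 0.7, "4" = 0.3),
                       decoys_per_genome = 0, seed = 17)
  s <- generate_survey(cfg)
  gs <- group_statistics(summarize_genomes(truth_hits(s), s$manifest))
  expect_equal(gs$count_mode, 3L)
})

test_that("per-group report is internally consistent", {
  s <- generate_survey(survey_config(genomes_per_group = 4L, seed = 19))
  gs <- group_statistics(summarize_genomes(truth_hits(s), s$manifest))
  expect_equal(gs$pct_N + gs$pct_middle + gs$pct_C, rep(100, nrow(gs)),
               tolerance = 1e-9)
  npos <- vapply(gs$count_histogram, sum, numeric(1))
  truthpos <- table(s$truth$group[s$truth$clade_index > 0],
                    s$truth$genome_id[s$truth$clade_index > 0])
  expect_equal(npos, vapply(gs$group, function(g)
    sum(truthpos[g, ] > 0), numeric(1), USE.NAMES = FALSE),
    ignore_attr = TRUE)
  # frequency distribution equals the truth-table distribution exactly
  for (g in gs$group) {
    truth_counts <- table(s$truth$genome_id[s$truth$clade_index > 0 &
                                              s$truth$group == g])
    hist <- gs$count_histogram[[match(g, gs$group)]]
    expect_equal(as.vector(hist), as.vector(table(as.integer(truth_counts))))
  }
})
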