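test_that("column frequencies exclude gaps and track occupancy", {
  cf <- column_frequencies(c("K", "K", "K"))
  expect_equal(unname(cf$freq[1, "K"]), 1)
  expect_equal(cf$occupancy, 1)

  cf2 <- column_frequencies(c("K", "K", "R", "-"))
  expect_equal(unname(cf2$freq[1, "K"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(cf2$freq[1, "R"]), 1 / 3, tolerance = 1e-12)
  expect_equal(cf2$occupancy, 0.75)

  # all-gap column: undefined frequencies, occupancy 0, ic 0
  logo0 <- consensus_logo(c("A-", "A-"), "z")
  expect_equal(logo0$occupancy[2], 0)
  expect_equal(logo0$ic[2], 0)
  expect_identical(substr(logo0$consensus, 2, 2), "x")
})

test_that("random frequency tables equal an exhaustive recount", {
  withr::with_seed(41, {
    ms <- vapply(1:50, function(i)
      paste(sample(c(aa_alphabet(), "-"), 180, replace = TRUE),
            collapse = ""), "")
  })
  cf <- column_frequencies(ms)
  m <- do.call(rbind, strsplit(ms, ""))
  for (j in c(1, 57, 180)) {
    col <- m[, j][m[, j] != "-"]
    for (a in unique(col)) {
      expect_equal(unname(cf$freq[j, a]), sum(col == a) / length(col),
                   tolerance = 1e-12)
    }
    expect_equal(cf$occupancy[j], length(col) / 50)
  }
})

test_that("information content matches its closed forms", {
  expect_equal(information_content(rep(1 / 20, 20)), 0, tolerance = 1e-12)
  one <- c(1, rep(0, 19))
  expect_equal(information_content(one), log2(20), tolerance = 1e-12)
  expect_equal(round(information_content(one), 4), 4.3219)
  half <- c(0.5, 0.5, rep(0, 18))
  expect_equal(information_content(half), log2(20) - 1, tolerance = 1e-12)
  # small-sample correction subtracts 19 / (2 ln2 n)
  expect_equal(information_content(one, n_residues = 10,
                                   small_sample_correction = TRUE),
               log2(20) - 19 / (2 * log(2) * 10), tolerance = 1e-12)
})

test_that("ic decreases when a column is mixed toward uniform", {
  withr::with_seed(43, {
    for (rep in 1:20) {
      f <- stats::runif(20); f <- f / sum(f)
      lam <- stats::runif(1)
      mixed <- (1 - lam) * f + lam * rep(1 / 20, 20)
      expect_lte(information_content(mixed), information_content(f) + 1e-12)
    }
  })
})

test_that("consensus takes the modal residue with alphabetical ties", {
  # freq(K) = 0.6 beats the rest
  logo <- consensus_logo(c("K", "K", "K", "R", "A"), "t")
  expect_identical(logo$consensus, "K")
  # K and R tied 2:2 -> alphabetically first (K) wins
  logo2 <- consensus_logo(c("K", "K", "R", "R"), "t")
  expect_identical(logo2$consensus, "K")
  # occupancy below the floor gives x
  logo3 <- consensus_logo(c("K", "-", "-", "-"), "t")
  expect_identical(consensus_sequence(logo3, min_occupancy = 0.5), "x")

  # consensus of a single gapless sequence is that sequence
  s <- random_aa(80, seed = 44)
  logo4 <- consensus_logo(s, "single")
  expect_identical(logo4$consensus, s)
})

test_that("conserved and dominant calls follow their definitions", {
  # all clades invariant G: conserved and dominant
  lg <- function(x) consensus_logo(x, "c")
  logos <- list(lg(rep("G", 5)), lg(rep("G", 5)), lg(rep("G", 5)))
  cs <- call_conserved_sites(logos)
  expect_equal(cs$positions, 1L)
  expect_equal(cs$dominant_positions, 1L)

  # invariant but different residues: conserved, not dominant
  logos2 <- list(lg(rep("G", 5)), lg(rep("A", 5)), lg(rep("G", 5)))
  cs2 <- call_conserved_sites(logos2)
  expect_equal(cs2$positions, 1L)
  expect_length(cs2$dominant_positions, 0L)

  # dominant is always a subset of conserved on random input
  withr::with_seed(45, {
    for (rep in 1:5) {
      rls <- lapply(1:4, function(k) {
        ms <- vapply(1:8, function(i)
          paste(sample(c("G", "A", "K", "-"), 30, replace = TRUE),
                collapse = ""), "")
        consensus_logo(ms, sprintf("c%d", k))
      })
      cs3 <- call_conserved_sites(rls)
      expect_true(all(cs3$dominant_positions %in% cs3$positions))
    }
  })
})

test_that("planted clade consensus reproduces its ancestor", {
  fam <- simulate_family(n_clades = 3, members_per_clade = 20,
                         between_clade_divergence = 0.3,
                         within_clade_divergence = 0.05, seed = 46)
  ms <- setNames(fam$members$match_string, fam$members$id)
  motif_idx <- which(fam$motif_mask)
  for (cl in 1:3) {
    logo <- consensus_logo(ms[fam$members$clade == cl], "c")
    cons <- strsplit(logo$consensus, "")[[1]]
    anc <- strsplit(fam$ancestors[cl], "")[[1]]
    expect_gte(mean(cons[motif_idx] == anc[motif_idx]), 0.95)
  }
})

test_that("motif segmentation finds the three planted blocks", {
  fam <- simulate_family(n_clades = 21, members_per_clade = 10,
                         between_clade_divergence = 0.9,
                         within_clade_divergence = 0.05, seed = 47)
  ms <- setNames(fam$members$match_string, fam$members$id)
  pooled <- consensus_logo(ms, "pooled")
  segs <- suppressWarnings(motif_segments(pooled))
  expect_equal(nrow(segs), 3L)
  tru <- do.call(rbind, fam$motif_cols)
  expect_true(all(abs(as.matrix(segs[, c("start", "end")]) - tru) <= 2))

  # a fully conserved profile collapses to one run, with a warning
  expect_warning(one <- motif_segments(rep(TRUE, 50)), "1 conserved run")
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 1L)
  expect_equal(one$end, 50L)

  # no conserved columns: empty result, warning
  expect_warning(none <- motif_segments(rep(FALSE, 50)), "no conserved")
  expect_equal(nrow(none), 0L)
})

test_that("logo tables carry chemistry classes for plotting", {
  logo <- consensus_logo(c("GKD", "GKD", "GKD"), "c")
  tab <- logo_table(logo)
  expect_equal(tab$chemistry, c("polar", "basic", "acidic"))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$ic, rep(log2(20), 3), tolerance = 1e-9)
})
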