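test_that("clade names follow the three-letter-group convention", {
  expect_identical(name_clade("Pezizomycotina", "VosA"), "Pez-VosA")
  expect_identical(
    name_clade(c("Saccharomycotina", "Taphrinomycotina"), "VelB"),
    "Sac-Tap-VelB")
  expect_identical(
    name_clade(c("Blastocladiomycota", "Cryptomycota"), "Velvet1"),
    "Bla-Cry-Velvet1")
  expect_error(name_clade(character(0), "VeA"))
})

test_that("reference-anchored assignment recovers planted clades exactly", {
  aln <- simulate_seed_alignment(seed = 2)
  prof <- build_profile(aln)
  s <- generate_survey(survey_config(seed = 31))
  cl <- survey_clades(s, prof)
  truth <- s$truth[s$truth$clade_index > 0, ]
  assigned <- tidyr::unnest(cl$assignments[, c("anchor", "member_ids")],
                            "member_ids")
  expect_setequal(assigned$member_ids, truth$protein_id)
  m <- merge(assigned, truth, by.x = "member_ids", by.y = "protein_id")
  expect_equal(rand_index(m$anchor, m$clade_index), 1)
  # the partition property: no leaf lost or duplicated
  expect_equal(anyDuplicated(assigned$member_ids), 0L)
  # names carry every group present in the clade
  named <- cl$assignments
  expect_true(all(grepl("-Ve|-Vo", named$clade_name)))
})

test_that("without references every leaf lands in a VelvetN clade", {
  fam <- simulate_family(n_clades = 3, members_per_clade = 5,
                         between_clade_divergence = 0.35,
                         within_clade_divergence = 0.04, seed = 21)
  ms <- c(setNames(fam$members$match_string, fam$members$id),
          outgroup = fam$outgroup)
  tree <- nj_tree(pairwise_distance(ms))
  asg <- assign_clades(tree, setNames(character(0), character(0)),
                       "outgroup")
  expect_true(all(grepl("^Velvet", asg$anchor)))
  expect_setequal(unlist(asg$member_ids), fam$members$id)
  expect_equal(anyDuplicated(unlist(asg$member_ids)), 0L)
  # numbered in decreasing size
  expect_true(all(diff(asg$n_members) <= 0))
})

test_that("a reference-free clan emerges as a VelvetN clade", {
  # references sit only in clan 1 (clades 1 and 3); the reference-free
  # clan 2 (clades 2 and 4) must come out as a new numbered clade
  fam <- simulate_family(n_clades = 4, members_per_clade = 8, n_clans = 2,
                         clan_divergence = 0.5,
                         between_clade_divergence = 0.3,
                         within_clade_divergence = 0.05, seed = 77)
  ms <- c(setNames(fam$members$match_string, fam$members$id),
          ref_VelB = fam$ancestors[1], ref_VosA = fam$ancestors[3],
          outgroup = fam$outgroup)
  tree <- nj_tree(pairwise_distance(ms))
  asg <- assign_clades(tree, c(ref_VelB = "VelB", ref_VosA = "VosA"),
                       "outgroup")
  expect_true("Velvet1" %in% asg$anchor)
  v1 <- unlist(asg$member_ids[asg$anchor == "Velvet1"])
  expect_setequal(v1, fam$members$id[fam$members$clade %in% c(2, 4)])
  expect_setequal(unlist(asg$member_ids[asg$anchor == "VelB"]),
                  fam$members$id[fam$members$clade == 1])
  expect_setequal(unlist(asg$member_ids[asg$anchor == "VosA"]),
                  fam$members$id[fam$members$clade == 3])
})

test_that("a reference sister to the outgroup is a flagged singleton", {
  txt <- "((ref_VeA:1.0,outgroup:1.0):0.5,((a:0.1,ref_VelB:0.1):0.8,(c:0.1,d:0.1):0.8):0.5);"
  tree <- ape::read.tree(text = txt)
  asg <- assign_clades(tree, c(ref_VeA = "VeA", ref_VelB = "VelB"),
                       "outgroup")
  ref_row <- asg[asg$anchor == "VeA", ]
  expect_true(ref_row$singleton)
  expect_equal(ref_row$n_members, 0L)
  # the other reference claims the whole remaining ingroup
  expect_setequal(unlist(asg$member_ids[asg$anchor == "VelB"]),
                  c("a", "c", "d"))
})

test_that("low-support subtrees are split when cutting new clades", {
  txt <- "(outgroup:2,((a:0.1,b:0.1)90:0.5,(c:0.1,d:0.1)30:0.5)40:1);"
  tree <- ape::read.tree(text = txt)
  asg <- assign_clades(tree, setNames(character(0), character(0)),
                       "outgroup", support_threshold = 50)
  # the 4-leaf subtree fails at support 40, so it splits:
  # (a,b) holds together at support 90; (c,d) at 30 splits into leaves
  sizes <- sort(asg$n_members, decreasing = TRUE)
  expect_equal(sizes, c(2L, 1L, 1L))
  two <- asg$member_ids[[which(asg$n_members == 2L)]]
  expect_setequal(two, c("a", "b"))
})

test_that("clade recovery holds across seeds at 6x divergence ratio", {
  aln <- simulate_seed_alignment(seed = 2)
  prof <- build_profile(aln)
  for (seed in c(101, 202)) {
    s <- generate_survey(survey_config(genomes_per_group = 4L, seed = seed))
    cl <- survey_clades(s, prof)
    truth <- s$truth[s$truth$clade_index > 0, ]
    assigned <- tidyr::unnest(cl$assignments[, c("anchor", "member_ids")],
                              "member_ids")
    m <- merge(assigned, truth, by.x = "member_ids", by.y = "protein_id")
    expect_gte(rand_index(m$anchor, m$clade_index), 0.99)
  }
})

test_that("clan partition follows planted ancestry and errors honestly", {
  # two tight pairs, each holding one anchor
  txt <- "((A:0.05,B:0.05):1,(C:0.05,D:0.05):1);"
  tree <- ape::read.tree(text = txt)
  cp <- clan_partition(tree, velb_anchor = "A", vosa_anchor = "C")
  expect_setequal(cp$VelB, c("A", "B"))
  expect_setequal(cp$VosA, c("C", "D"))
  expect_error(clan_partition(tree, "A", "B"), "same subtree")
  expect_error(clan_partition(tree, "A", "Z"), "leaves")

  # planted two-clan family: consensus tree splits along clan ancestry
  fam <- simulate_family(n_clades = 4, members_per_clade = 20, n_clans = 2,
                         clan_divergence = 0.5,
                         between_clade_divergence = 0.3,
                         within_clade_divergence = 0.05, seed = 9)
  ms <- setNames(fam$members$match_string, fam$members$id)
  memb <- split(fam$members$id, fam$members$clade)
  names(memb) <- sprintf("clade%02d", 1:4)
  logos <- clade_logos(ms, memb)
  ctree <- clade_consensus_tree(logos)
  velb_leaf <- sprintf("clade%02d", which(fam$clan_of_clade == 1)[1])
  vosa_leaf <- sprintf("clade%02d", which(fam$clan_of_clade == 2)[1])
  cp2 <- clan_partition(ctree, velb_leaf, vosa_leaf)
  expect_setequal(cp2$VelB,
                  sprintf("clade%02d", which(fam$clan_of_clade == 1)))
  expect_setequal(cp2$VosA,
                  sprintf("clade%02d", which(fam$clan_of_clade == 2)))
})
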