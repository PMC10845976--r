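#!/usr/bin/env Rscript
# Stage 4: phylogeny, bootstrap and reference-anchored clades.
#
# Builds Poisson-corrected distances over the profile match strings of all
# surviving proteins plus the four reference anchors and the outgroup,
# infers the neighbor-joining tree with 100 bootstrap replicates, roots on
# the outgroup, assigns VeA/VelB/VelC/VosA clades, and compares clade
# protein-length distributions with pairwise unpaired t-tests.

suppressMessages(library(velvetsurvey))
seed <- 1L

# the survey is regenerated deterministically; its family block carries the
# reference ancestors and the outgroup sequence
survey <- generate_survey(survey_config(seed = seed))
profile <- read_profile("results/profile")
kept <- utils::read.delim("results/hits_full.tsv")
kept <- tibble::as_tibble(kept)

cl <- survey_clades(survey, profile, hits = kept, n_bootstrap = 100,
                    seed = seed)
ape::write.tree(cl$tree, "results/survey_tree.nwk")

flat <- tidyr::unnest(
  cl$assignments[, c("clade_name", "anchor", "member_ids")], "member_ids")
names(flat)[names(flat) == "member_ids"] <- "protein_id"
utils::write.table(flat[order(flat$clade_name, flat$protein_id), ],
                   "results/clades.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

truth <- survey$truth[survey$truth$clade_index > 0, ]
m <- merge(flat, truth, by = "protein_id")
cat(sprintf("assigned %d proteins to %d clades; Rand index vs truth: %.4f\n",
            nrow(flat), nrow(cl$assignments),
            rand_index(m$anchor, m$clade_index)))
cat("clades:\n")
print(as.data.frame(cl$assignments[, c("clade_name", "anchor", "n_members",
                                       "singleton")]))

# clade protein-length comparisons (box summaries + pairwise t-tests)
lengths_by_clade <- split(
  kept$protein_length[match(flat$protein_id, kept$protein_id)],
  flat$clade_name)
cat("\nclade protein-length box summaries:\n")
for (nm in names(lengths_by_clade)) {
  b <- box_summary(lengths_by_clade[[nm]])
  cat(sprintf("  %-28s n=%3d mean=%.0f median=%.0f IQR=[%.0f, %.0f]\n",
              nm, b$n, b$mean, b$median, b$q1, b$q3))
}
tests <- pairwise_ttests(lengths_by_clade)
utils::write.table(tests, "results/clade_length_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\npairwise unpaired t-tests written to results/clade_length_tests.tsv\n")
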