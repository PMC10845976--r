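#!/usr/bin/env Rscript
# Stage 3: per-group survey statistics.
#
# Summarizes surviving hits per genome and reports, per taxonomic group,
# the percentage of genomes with velvet genes, the per-genome count mode,
# mean protein and domain lengths, and the N/middle/C domain-position
# distribution under the midpoint rule.

suppressMessages(library(velvetsurvey))

kept <- utils::read.delim("results/hits.tsv")
manifest <- utils::read.delim("results/survey/manifest.tsv")
summaries <- summarize_genomes(kept, manifest)
gs <- group_statistics(summaries)

utils::write.table(
  dplyr::select(gs, -dplyr::any_of("count_histogram")),
  "results/group_stats.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cat("per-group survey statistics:\n")
print(as.data.frame(dplyr::select(gs, -dplyr::any_of("count_histogram"))),
      digits = 4)
cat("\nper-genome count histograms (velvet-positive genomes only):\n")
for (i in seq_len(nrow(gs))) {
  h <- gs$count_histogram[[i]]
  cat(sprintf("  %-20s %s\n", gs$group[i],
              paste(names(h), h, sep = ":", collapse = "  ")))
}
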