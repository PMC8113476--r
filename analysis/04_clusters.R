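#!/usr/bin/env Rscript

# Stage 4 — tRNA gene clustering.
#
# Groups tRNA genes within 5 Mb of one another (bedtools-merge style
# single linkage) and keeps groups with at least 5 genes at a density of at
# least 5 genes/Mb, then asks where the age-hypermethylating tRNAs fall
# relative to those clusters.

suppressMessages(library(trnameth))

clusters <- run_cluster("scratch/study", "results")
summary4 <- read.delim("results/trna_summary_model4.tsv")
called <- summary4$feature[summary4$study_wide_significant]

member_list <- strsplit(clusters$members, ",")
in_cluster <- vapply(called, function(g) any(vapply(member_list, function(m)
  g %in% m, logical(1))), logical(1))

cat(sprintf("%d clusters hold %d of %d tRNA genes.\n", nrow(clusters),
            sum(clusters$n_genes), nrow(summary4)))
cat(sprintf("%d/%d significant tRNAs fall inside clusters.\n",
            sum(in_cluster), length(called)))
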