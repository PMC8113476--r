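#!/usr/bin/env Rscript

# Stage 5 — pooled targeted bisulfite replication.
#
# Emulates the pooled validation design: 8 pools of age-matched individuals
# at 4 time points (~4, 28, 63, 78 years; 190 contributors) sequenced over
# the tRNA loci called in stage 2 plus unaffected isodecoder controls, at
# ~679x median depth. The planted effect is 5e-4 proportion/yr at affected
# loci (~3.7% from age 4 to 78). Coverage-filtered counts (>= 25 reads) go
# through all pairwise age-group comparisons per region and the per-region
# pooled age regression.

suppressMessages(library(trnameth))

genes <- read_feature_bed("scratch/study/trna_genes.bed")
truth <- read.delim("scratch/study/truth.tsv")

# target affected loci plus an equal number of unaffected controls
set.seed(2028)
controls <- sample(setdiff(genes$name, truth$affected_gene),
                   nrow(truth))
targets <- genes[genes$name %in% c(truth$affected_gene, controls), ]

design <- pool_design_default()
sites <- trna_cpg_sites(targets, seed = 2029)
counts <- simulate_pooled_bis(design, sites, baseline_meth = 0.02,
                              slope_per_year = 5e-4,
                              affected = truth$affected_gene,
                              coverage_mean = 679, seed = 2030)

out <- run_bis_diff(counts, design, "results", min_reads = 25)

extreme <- out$pairwise[out$pairwise$comparison == "4 vs. 78", ]
extreme <- extreme[order(extreme$p_value), ]
cat("Top 4 vs. 78 pairwise differences (delta = older - younger):\n")
print(head(extreme[, c("feature", "num_cpgs", "p_value", "delta")], 8),
      row.names = FALSE)
aff <- extreme$feature %in% truth$affected_gene
cat(sprintf("Mean delta at affected loci %.4f; at controls %.4f\n",
            mean(extreme$delta[aff]), mean(extreme$delta[!aff])))
reg <- out$regression
cat(sprintf("Pooled age regression: %d/%d affected loci at p < 0.05 vs \
%d/%d controls\n",
            sum(reg$p_value[reg$feature %in% truth$affected_gene] < 0.05),
            sum(reg$feature %in% truth$affected_gene),
            sum(reg$p_value[!reg$feature %in% truth$affected_gene] < 0.05),
            sum(!reg$feature %in% truth$affected_gene)))
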