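#!/usr/bin/env Rscript

# Stage 6: differential analysis of high- vs low-heterosis hybrids.
# The diallel population is split at its BPH-YPP tails (72 hybrids each);
# PLS-DA separates the subgroups (validated by stratified CV and label
# permutation), analyte-wise pooled t tests with Benjamini-Hochberg control
# count the differential analytes, and their overlap with the PLS-selected
# predictive variables is tabulated. A pathway-style comparison averages the
# planted module members per hybrid.

suppressPackageStartupMessages(library(metaheterosis))

in_dir <- "results/simulated_study"
mm <- read_metabolite_table(file.path(in_dir, "metabolites.csv"),
                            meta = file.path(in_dir, "sample_meta.csv"))
phenos <- read_phenotypes(file.path(in_dir, "phenotypes.csv"))
design <- read_design(file.path(in_dir, "design.csv"))

parents <- normalize_metabolites(average_replicates(
  filter_samples(mm, roles = "parent")))
pv <- transform_parents(parents, design, "means")
het <- compute_bph(phenos, design)
het1 <- het[het$population == "pop1", ]

labels <- split_by_quantiles(het1, n_per_group = 72L)
cat(sprintf("subgroups: %d high / %d low (cuts %.3f / %.3f)\n",
            labels$counts["high"], labels$counts["low"],
            labels$cuts["high"], labels$cuts["low"]))

da <- fit_plsda(pv$values, labels, A = 2)
cv <- cross_validate_plsda(pv$values, labels, folds = 6, A_grid = 1:3,
                           seed = 1)
print(cv)
perm <- permutation_test_plsda(pv$values, labels, n_perm = 1000, seed = 1)
cat(sprintf("PLS-DA permutation test: statistic %.2f, p = %.4g\n",
            perm$statistic, perm$p.value))
top1000 <- top_k_by_vip(vip(da, components = 1), 1000L)
cat(sprintf("top-1000 component-1 VIP cutoff: %.4f\n", top1000$threshold))

hi <- names(labels$labels)[labels$labels == "high"]
lo <- names(labels$labels)[labels$labels == "low"]
dres <- test_analytes(pv$values[hi, ], pv$values[lo, ], alpha = 0.05)
utils::write.table(as.data.frame(dres), file.path(in_dir, "differential.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d analytes differ at FDR 0.05\n",
            sum(dres$significant), nrow(dres)))

ov <- selection_overlap(top1000$ids, dres$analyte_id[dres$significant])
cat(sprintf("overlap with top-1000 PLS-DA selection: %d shared, %d PLS-only, %d t-test-only\n",
            ov$intersection, ov$only_a, ov$only_b))

truth <- jsonlite::read_json(file.path(in_dir, "truth.json"),
                             simplifyVector = TRUE)
pm <- pathway_mean_compare(pv$values, truth$planted_ids, labels)
cat(sprintf("planted-module mean level: high %.3f vs low %.3f (t = %.2f, p = %.3g)\n",
            pm$group_means["high"], pm$group_means["low"],
            pm$statistic, pm$p.value))
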