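#!/usr/bin/env Rscript

# Stage 3: better-parent heterosis and predictive variables.
# BPH-YPP = (F1 - PH)/PH per hybrid from replicate-mean yields; parental
# metabolite profiles are combined per hybrid as means, differences and
# ratios, and compared against the measured profiles of the reciprocal
# hybrids that were themselves put on the instrument. Parental means track
# hybrid metabolomes best and are used as the predictive variables.

suppressPackageStartupMessages(library(metaheterosis))

in_dir <- "results/simulated_study"
mm <- read_metabolite_table(file.path(in_dir, "metabolites.csv"),
                            meta = file.path(in_dir, "sample_meta.csv"))
phenos <- read_phenotypes(file.path(in_dir, "phenotypes.csv"))
design <- read_design(file.path(in_dir, "design.csv"))

het <- compute_bph(phenos, design)
utils::write.table(as.data.frame(het), file.path(in_dir, "heterosis.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("BPH-YPP: mean %.3f, range [%.3f, %.3f] over %d hybrids\n",
            mean(het$BPH_YPP), min(het$BPH_YPP), max(het$BPH_YPP),
            nrow(het)))

parents_raw <- average_replicates(filter_samples(mm, roles = "parent"))
hybrids_raw <- average_replicates(filter_samples(mm, roles = "hybrid"))
r_means <- compare_hybrid_to_transforms(
  hybrids_raw, transform_parents(parents_raw, design, "means"))$r
r_diff <- compare_hybrid_to_transforms(
  hybrids_raw, transform_parents(parents_raw, design, "differences"))$r
r_ratio <- compare_hybrid_to_transforms(
  hybrids_raw, transform_parents(sum_normalize(parents_raw), design,
                                 "ratios"))$r
cat(sprintf("hybrid-profile correlation: means %.3f > differences %.3f, ratios %.3f\n",
            mean(r_means), mean(r_diff), mean(r_ratio)))
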