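#!/usr/bin/env Rscript

# Stage 2: quality filtering and normalization of the metabolite table.
# QC injections are set aside, biological replicates averaged per genotype,
# every sample row sum-normalized to a common total, and every analyte
# autoscaled to mean 0 / SD 1 (the standard untargeted-LC-MS recipe:
# normalization by sum, no transformation, autoscaling).

suppressPackageStartupMessages(library(metaheterosis))

in_dir <- "results/simulated_study"
mm <- read_metabolite_table(file.path(in_dir, "metabolites.csv"),
                            meta = file.path(in_dir, "sample_meta.csv"))
cat("raw table: "); print(mm)

parents <- filter_samples(mm, roles = c("parent", "maintainer"))
parents <- normalize_metabolites(average_replicates(parents))
cat("normalized parents: "); print(parents)

write_metabolite_table(parents,
                       file.path(in_dir, "parents_normalized.tsv"),
                       meta_path = file.path(in_dir, "parents_meta.tsv"))
cat("column-mean |max| after autoscaling:",
    format(max(abs(colMeans(parents$values))), digits = 3), "\n")
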