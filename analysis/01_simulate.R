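#!/usr/bin/env Rscript

# Stage 1: generate the synthetic two-population study and write it to disk
# in the same delimited formats a real study would arrive in.
#
# The study mirrors the shape of the motivating field design: an 18-parent
# complete diallel (306 hybrids, reciprocals included) plus 107 inbred lines
# test-crossed to one CMS female, 2,000 LC-MS analytes of which 200 form a
# planted heterosis-associated module explaining half the BPH-YPP variance.

suppressPackageStartupMessages(library(metaheterosis))

out_dir <- "results/simulated_study"
cfg <- synthetic_config(seed = 1)
bundle <- generate_synthetic(cfg)
export_fixture(bundle, out_dir)

cat("Simulated study written to", out_dir, "\n")
print(bundle$metabolites)
cat(sprintf("hybrids: %d (pop1 %d diallel + pop2 %d testcross)\n",
            nrow(bundle$design),
            sum(bundle$design$population == "pop1"),
            sum(bundle$design$population == "pop2")))
cat(sprintf("planted analytes: %d of %d; heterosis noise SD %.3f\n",
            length(bundle$truth$planted_ids), cfg$p, bundle$truth$sigma_y))
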