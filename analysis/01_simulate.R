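#!/usr/bin/env Rscript
# Generate a small on-disk demonstration dataset: two cells per drug
# condition as two-channel TIFF stacks with ground-truth tables and a
# manifest. The statistical analyses (03) regenerate larger experiments
# in memory; this script exists to exercise and document the on-disk
# interchange format.

library(nascentq)

out <- "results/demo_dataset"
manifest <- generate_experiment(condition_presets(), n_cells_per_condition = 2,
                                seed = 11, out_dir = out)
cat("Wrote", nrow(manifest), "cells to", out, "\n")
print(manifest[, c("condition", "cell", "n_mRNA", "mrna_tiff")])

# sanity: the stacks round-trip and the ground truth re-loads
st <- read_stack(file.path(out, manifest$mrna_tiff[1]))
gt <- read_ground_truth(file.path(out, manifest$truth_csv[1]))
cat(sprintf("First cell: %d x %d x %d stack, %d mRNAs (%d translating)\n",
            dim(st)[1], dim(st)[2], dim(st)[3], nrow(gt$mrna),
            sum(gt$mrna$translating)))
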