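#!/usr/bin/env Rscript
# The diffusion spatial-resolution argument: how far a released protein
# (cytosolic D = 126 um^2/s) travels during common metabolic-labeling
# pulse times, in 1, 2 and 3 dimensions.

library(nascentq)

cat(sprintf("1D RMS displacement after 60 s: %.2f um\n",
            rms_displacement(126, 1, 60)))
cat(sprintf("Time to reach 100 um (1D): %.2f s\n",
            time_to_reach(126, 1, 100)))
cat(sprintf("Time to reach 100 um (2D): %.2f s\n",
            time_to_reach(126, 2, 100)))
cat(sprintf("3D RMS displacement after 10 s: %.2f um\n",
            rms_displacement(126, 3, 10)))

curves <- displacement_curve(126, t_grid = seq(0, 300, by = 5))
dir.create("results", showWarnings = FALSE)
write.csv(curves, "results/diffusion_curves.csv", row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(curves, aes(t, displacement_um, color = factor(n))) +
    geom_line(linewidth = 0.7) +
    labs(x = "time (s)", y = "expected RMS displacement (um)",
         color = "dimensions") +
    theme_classic()
  ggsave("results/diffusion_curves.png", p, width = 5, height = 3.5)
  cat("Wrote results/diffusion_curves.png\n")
}
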