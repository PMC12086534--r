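#!/usr/bin/env Rscript
# Generate the three synthetic study designs (high- vs low-capacity rats on
# 1-week diets, voluntary-wheel-running mice, and liver-specific Cyp7a1
# knockout mice) and write their CSV tables under results/synthetic/.
# The truth tables written alongside are for scoring only; the downstream
# drivers never read them.

suppressPackageStartupMessages(library(d2otrace))

out_root <- "results/synthetic"
for (preset in c("hcr_lcr_1wk", "vwr_mice", "lcyp7a1ko")) {
  cfg <- preset_study(preset)
  st <- simulate_study(cfg)
  dir <- file.path(out_root, preset)
  write_study(st, dir)
  cat(sprintf("%-12s %3d animals x %d analytes -> %s\n",
              preset, sum(cfg$groups$size), nrow(cfg$analytes), dir))
}
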