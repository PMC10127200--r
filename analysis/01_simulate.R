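#!/usr/bin/env Rscript
# Generate the synthetic multi-cell-line screen analysed in the rest of the
# workflow: 6 cell lines, 20 MOAs x 5 compounds, one plate per line with 8
# DMSO wells, 200 cells/well, 77 features. Effects differ by (MOA, line) so
# lines have genuinely different detection profiles; line 4 is planted as
# the overall most sensitive (largest effects on most MOAs).

library(phenopanel)

dir.create("scratch/analysis", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

# Planted effects straddle the assay's detection threshold (at 200
# cells/well and 77 features, displacements around 0.5-1 noise SD are
# partially detectable), so lines genuinely differ and panel choice matters.
set.seed(101)
n_moas <- 20; n_lines <- 6
a <- matrix(runif(n_moas * n_lines, 0, 1.2), n_moas, n_lines)
a[, 4] <- a[, 4] + 0.4  # line_04 planted as the most sensitive line
tau <- runif(n_moas, 0.1, 1.0)  # MOAs vary in compound coherence

cfg <- synthetic_screen_config(
  n_cell_lines = n_lines, n_features = 77, n_moas = n_moas,
  compounds_per_moa = 5, dmso_wells_per_plate = 8, cells_per_well = 200,
  effect_magnitude = a, heterogeneity = tau, seed = 2026)

screen <- generate_screen(cfg)
message(sprintf("screen: %d cells, %d compounds, %d cell lines",
                nrow(screen$cells), length(screen$truth$compounds),
                n_lines))

saveRDS(screen, "scratch/analysis/screen.rds")
saveRDS(cfg, "scratch/analysis/config.rds")
write.csv(data.frame(compound = screen$annotation$compound,
                     moa = screen$annotation$moa),
          "results/annotation.csv", row.names = FALSE)
message("saved scratch/analysis/screen.rds and results/annotation.csv")
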