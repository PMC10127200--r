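#!/usr/bin/env Rscript
# Rank single cell lines and pairs by max-aggregated panel summaries, with
# compound-subsampling robustness (50 draws, 2/3 of compounds retained), and
# report the improvement of the best pair over the best single line.

library(phenopanel)

screen <- readRDS("scratch/analysis/screen.rds")
profiles <- readRDS("scratch/analysis/profiles.rds")

for (task in c("phenoactivity", "phenosimilarity")) {
  rk <- rank_sets(profiles, screen$annotation, task, max_set_size = 2,
                  min_moa_size = 5, n_draws = 50, fraction = 2 / 3,
                  seed = 17)
  out <- rk[, c("lines", "task", "n_lines", "n_moas", "summary",
                "subsample_mean", "subsample_sd")]
  path <- sprintf("results/panel_ranking_%s.csv", task)
  write.csv(out, path, row.names = FALSE)

  best1 <- rk[rk$n_lines == 1, ][1, ]
  best2 <- rk[rk$n_lines == 2, ][1, ]
  message(sprintf(
    "%s: best line %s (summary %.3f), best pair %s (summary %.3f), improvement %.1f%%",
    task, best1$lines, best1$summary, best2$lines, best2$summary,
    improvement(best1$summary, best2$summary)))
  message(sprintf(
    "  subsample robustness: best line %.3f +/- %.3f, best pair %.3f +/- %.3f",
    best1$subsample_mean, best1$subsample_sd,
    best2$subsample_mean, best2$subsample_sd))
  message("saved ", path)
}
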