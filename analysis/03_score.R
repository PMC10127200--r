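#!/usr/bin/env Rscript
# Score every (cell line, MOA) pair for phenoactivity (separation from the
# DMSO cloud) and phenosimilarity (tightness relative to each compound's
# nearest neighbors), with the 5-compound reporting filter.

library(phenopanel)

screen <- readRDS("scratch/analysis/screen.rds")
profiles <- readRDS("scratch/analysis/profiles.rds")

pa <- score_all_phenoactivity(profiles, screen$annotation, min_moa_size = 5)
ps <- score_all_phenosimilarity(profiles, screen$annotation,
                                min_moa_size = 5)

write_scores(pa, "results/phenoactivity.csv")
write_scores(ps, "results/phenosimilarity.csv")

per_line <- function(tbl) {
  agg <- stats::aggregate(score ~ cell_line, data = tbl, FUN = mean)
  agg[order(-agg$score), ]
}
message("mean phenoactivity by line (best first):")
print(per_line(pa), row.names = FALSE)
message("mean phenosimilarity by line (best first):")
print(per_line(ps), row.names = FALSE)
message(sprintf("compounds outside the DMSO cloud: %d / %d",
                sum(pa$n_outside), sum(pa$n_compounds)))
message("saved results/phenoactivity.csv and results/phenosimilarity.csv")
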