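#!/usr/bin/env Rscript
# Reduce the per-cell screen to signed-KS phenotypic profiles: one pooled
# profile per (cell line, compound) plus leave-one-well-out DMSO
# self-profiles per line.

library(phenopanel)

screen <- readRDS("scratch/analysis/screen.rds")
profiles <- build_profiles(screen$cells)

n_cmpd <- sum(profiles$role == "compound")
n_ctrl <- sum(profiles$role == "control")
message(sprintf("built %d compound profiles and %d DMSO self-profiles (%d features)",
                n_cmpd, n_ctrl, length(feature_names(profiles))))
m <- profile_matrix(profiles)
message(sprintf("profile entries span [%.3f, %.3f]", min(m), max(m)))

saveRDS(profiles, "scratch/analysis/profiles.rds")
message("saved scratch/analysis/profiles.rds")
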