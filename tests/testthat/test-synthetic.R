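test_that("config validation names the offending field", {
  expect_error(synthetic_screen_config(n_cell_lines = 0), "n_cell_lines")
  expect_error(synthetic_screen_config(cells_per_well = 2.5),
               "cells_per_well")
  expect_error(synthetic_screen_config(effect_magnitude = -1),
               "effect_magnitude")
  expect_error(synthetic_screen_config(n_moas = 3,
                                       heterogeneity = c(0.1, 0.2)),
               "heterogeneity")
  expect_error(synthetic_screen_config(n_moas = 4,
                                       effect_magnitude = matrix(1, 2, 2)),
               "effect_magnitude")
  expect_error(synthetic_screen_config(cell_model = "t", t_df = 2), "t_df")
})

test_that("screens are deterministic functions of the config", {
  cfg <- synthetic_screen_config(n_cell_lines = 2, n_features = 6,
                                 n_moas = 2, compounds_per_moa = 2,
                                 dmso_wells_per_plate = 3,
                                 cells_per_well = 15, seed = 12)
  s1 <- generate_screen(cfg)
  s2 <- generate_screen(cfg)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$annotation, s2$annotation)
  # a different seed changes the data
  cfg2 <- synthetic_screen_config(n_cell_lines = 2, n_features = 6,
                                  n_moas = 2, compounds_per_moa = 2,
                                  dmso_wells_per_plate = 3,
                                  cells_per_well = 15, seed = 13)
  expect_false(identical(generate_screen(cfg2)$cells, s1$cells))
})

test_that("ground truth obeys the planted-effect decomposition", {
  a <- matrix(runif(6, 0.5, 2), 3, 2)
  cfg <- synthetic_screen_config(n_cell_lines = 2, n_features = 10,
                                 n_moas = 3, compounds_per_moa = 2,
                                 dmso_wells_per_plate = 2,
                                 cells_per_well = 5, effect_magnitude = a,
                                 heterogeneity = c(0.1, 0.4, 0.9), seed = 3)
  tr <- generate_screen(cfg)$truth
  # unit effect directions
  norms <- apply(tr$u, c(1, 2), function(x) sqrt(sum(x^2)))
  expect_equal(unname(norms), matrix(1, 3, 2))
  # v = a * u + tau * eps, with eps shared across lines
  for (ci in seq_along(tr$compounds)) {
    m <- ceiling(ci / 2)
    for (l in 1:2) {
      expect_equal(unname(tr$v[ci, l, ]),
                   a[m, l] * tr$u[m, l, ] +
                     cfg$heterogeneity[m] * unname(tr$eps[ci, ]))
    }
  }
  # compound wells are shifted by v in the mean: check via a huge-a config
  cfg2 <- synthetic_screen_config(n_cell_lines = 1, n_features = 4,
                                  n_moas = 1, compounds_per_moa = 1,
                                  dmso_wells_per_plate = 2,
                                  cells_per_well = 2000,
                                  effect_magnitude = 50, heterogeneity = 0,
                                  seed = 8)
  scr2 <- generate_screen(cfg2)
  cmpd <- scr2$cells[scr2$cells$role == "compound", paste0("f_", 1:4)]
  expect_equal(unname(colMeans(as.matrix(cmpd))),
               unname(scr2$truth$v[1, 1, ]), tolerance = 0.05)
})

test_that("null screens are quiet and planted effects are recovered where planted", {
  # a = 0, tau = 0: compounds indistinguishable from DMSO
  set.seed(1)
  null_means <- vapply(1:5, function(s) {
    cfg <- synthetic_screen_config(n_cell_lines = 1, n_features = 77,
                                   n_moas = 4, compounds_per_moa = 3,
                                   dmso_wells_per_plate = 8,
                                   cells_per_well = 200,
                                   effect_magnitude = 0, heterogeneity = 0,
                                   seed = 400 + s)
    scr <- generate_screen(cfg)
    mean(score_all_phenoactivity(build_profiles(scr$cells),
                                 scr$annotation)$score)
  }, numeric(1))
  expect_lt(mean(null_means), 0.15)

  # under the null the outside-cloud rate for compounds matches the DMSO
  # self-rate within 3x the binomial standard error
  cfg <- synthetic_screen_config(n_cell_lines = 1, n_features = 10,
                                 n_moas = 8, compounds_per_moa = 5,
                                 dmso_wells_per_plate = 12,
                                 cells_per_well = 100,
                                 effect_magnitude = 0, heterogeneity = 0,
                                 seed = 555)
  scr <- generate_screen(cfg)
  prof <- build_profiles(scr$cells)
  res <- score_all_phenoactivity(prof, scr$annotation)
  n_cmpd <- sum(res$n_compounds)
  rate_cmpd <- sum(res$n_outside) / n_cmpd
  ctrl <- prof[prof$role == "control", ]
  ds <- distance_set(profile_matrix(phenotypic_profiles(ctrl)),
                     profile_matrix(phenotypic_profiles(ctrl)))
  thr <- outside_cloud(ds)$threshold
  rate_dmso <- mean(ds$dmso_distances > thr)
  se <- sqrt(rate_dmso * (1 - rate_dmso) / n_cmpd)
  expect_lte(abs(rate_cmpd - rate_dmso), max(3 * se, 3 * sqrt(0.25 / n_cmpd)))

  # a large effect planted in one (MOA, line) cell is highest there
  a <- matrix(0, 3, 2)
  a[2, 2] <- 4
  cfgp <- synthetic_screen_config(n_cell_lines = 2, n_features = 10,
                                  n_moas = 3, compounds_per_moa = 3,
                                  dmso_wells_per_plate = 6,
                                  cells_per_well = 60, effect_magnitude = a,
                                  heterogeneity = 0.1, seed = 777)
  scrp <- generate_screen(cfgp)
  resp <- score_all_phenoactivity(build_profiles(scrp$cells),
                                  scrp$annotation)
  top <- resp[which.max(resp$score), ]
  expect_equal(top$moa, "moa_02")
  expect_equal(top$cell_line, "line_02")
})

test_that("parameter recovery report sweeps grids and validates inputs", {
  base <- synthetic_screen_config(n_cell_lines = 1, n_features = 8,
                                  n_moas = 3, compounds_per_moa = 3,
                                  dmso_wells_per_plate = 4,
                                  cells_per_well = 25, effect_magnitude = 0,
                                  heterogeneity = 0, seed = 50)
  expect_error(parameter_recovery_report(base), "at least one")
  expect_error(parameter_recovery_report(base, effect_grid = 1),
               "degenerate grid")

  rep <- parameter_recovery_report(base, effect_grid = c(0, 3), n_seeds = 2)
  expect_equal(nrow(rep$results), 4)
  expect_true(all(c("mean_phenoactivity", "mean_phenosimilarity") %in%
                    names(rep$results)))
  expect_equal(nrow(rep$grid_means), 2)
  # a strong effect vs none orders the means even in a tiny sweep
  expect_gt(rep$grid_means$mean_phenoactivity[2],
            rep$grid_means$mean_phenoactivity[1])
  expect_equal(rep$summary$spearman_phenoactivity, 1)
})
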