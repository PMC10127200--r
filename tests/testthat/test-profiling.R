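test_that("signed KS statistic matches direct ECDF evaluation and handles edges", {
  expect_equal(signed_ks(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(signed_ks(c(10, 11, 12), c(1, 2, 3)), 1)
  expect_equal(signed_ks(c(1, 2, 3), c(10, 11, 12)), -1)
  expect_equal(signed_ks(c(1, 3), c(2, 4)), -0.5)
  # repeated values (multisets) are respected
  expect_equal(signed_ks(c(1, 1, 2), c(1, 2, 2)), -1 / 3)
  # exact branch tie (ABBA interleaving): sign from the first ECDF
  # difference, antisymmetric under sample swap
  expect_equal(signed_ks(c(1, 4), c(2, 3)), -0.5)
  expect_equal(signed_ks(c(2, 3), c(1, 4)), 0.5)
  expect_error(signed_ks(numeric(0), 1), "treated")
  expect_error(signed_ks(1, numeric(0)), "control")
})

test_that("signed KS is antisymmetric, rank-invariant, and agrees with ks.test", {
  set.seed(11)
  for (i in 1:200) {
    a <- rnorm(sample(2:12, 1))
    b <- rnorm(sample(2:12, 1), mean = runif(1, -1, 1))
    s <- signed_ks(a, b)
    expect_equal(s, -signed_ks(b, a))
    # strictly increasing transform leaves the statistic unchanged
    tr <- function(x) exp(x) + 2 * x
    expect_equal(signed_ks(tr(a), tr(b)), s)
    # magnitude equals the classical two-sample KS statistic
    expect_equal(abs(s),
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
  }
})

test_that("profiles are per-feature signed KS against plate-matched controls", {
  # 2-feature toy: 6 treated cells, 6 control cells
  treated <- matrix(c(2.0, 2.5, 3.0, 3.5, 4.0, 4.5,   # f_1 shifted up
                      0.1, -0.2, 0.3, -0.1, 0.2, 0.0), ncol = 2)
  control <- matrix(c(1.0, 1.2, 1.9, 2.1, 2.8, 3.1,
                      0.0, 0.1, -0.1, 0.2, -0.2, 0.3), ncol = 2)
  cells <- toy_cells(list(
    W1 = list(treatment = "cmpA", role = "compound", features = treated),
    D1 = list(treatment = "DMSO", role = "control", features = control)))
  prof <- build_profile(cells, "cmpA")
  expect_s3_class(prof, "phenotypic_profiles")
  expect_equal(prof$n_cells_treated, 6)
  expect_equal(prof$n_cells_control, 6)
  expect_equal(prof$f_1, signed_ks_oracle(treated[, 1], control[, 1]))
  expect_equal(prof$f_2, signed_ks_oracle(treated[, 2], control[, 2]))

  # identical treated and control cells give the zero vector
  cells0 <- toy_cells(list(
    W1 = list(treatment = "cmpA", role = "compound", features = control),
    D1 = list(treatment = "DMSO", role = "control", features = control)))
  prof0 <- build_profile(cells0, "cmpA")
  expect_equal(unname(unlist(prof0[, c("f_1", "f_2")])), c(0, 0))

  # a shift in one feature moves only that coordinate
  shifted <- control
  shifted[, 2] <- shifted[, 2] + 100
  prof1 <- build_profile(toy_cells(list(
    W1 = list(treatment = "cmpA", role = "compound", features = shifted),
    D1 = list(treatment = "DMSO", role = "control", features = control))),
    "cmpA")
  expect_equal(prof1$f_1, 0)
  expect_equal(prof1$f_2, 1)

  # cell row order is irrelevant
  perm <- cells[sample(nrow(cells)), ]
  prof2 <- build_profile(cell_feature_table(perm, feature_names(cells)),
                         "cmpA")
  expect_equal(as.data.frame(prof2), as.data.frame(prof))
})

test_that("treatments without same-plate controls are an error naming the plate", {
  # a compound plate without controls violates the table invariant, so this
  # malformed input is assembled without the validating constructor
  df <- tibble::tibble(
    cell_line = "L1", plate = rep(c("P1", "P2"), each = 4),
    well = rep(c("W1", "D1"), each = 4),
    treatment = rep(c("cmpA", "DMSO"), each = 4),
    role = rep(c("compound", "control"), each = 4),
    f_1 = rnorm(8), f_2 = rnorm(8))
  cells <- structure(df, features = c("f_1", "f_2"),
                     class = c("cell_feature_table", class(df)))
  expect_error(build_profile(cells, "cmpA"), "P1")
  # global pooling rescues it
  expect_s3_class(build_profile(cells, "cmpA", control_policy = "global"),
                  "phenotypic_profiles")
})

test_that("DMSO self-profiles are leave-one-well-out and degenerate wells are skipped", {
  m <- matrix(rnorm(12), ncol = 2)
  # two identical control wells -> both self-profiles exactly zero
  cells <- toy_cells(list(
    D1 = list(treatment = "DMSO", role = "control", features = m),
    D2 = list(treatment = "DMSO", role = "control", features = m)))
  ctrl <- build_control_profiles(cells)
  expect_equal(nrow(ctrl), 2)
  expect_true(all(ctrl$role == "control"))
  expect_equal(unname(as.vector(profile_matrix(ctrl))), rep(0, 4))

  # a plate with a single control well yields no profile, with a warning
  cells1 <- toy_cells(list(
    D1 = list(treatment = "DMSO", role = "control", features = m)))
  expect_warning(ctrl1 <- build_control_profiles(cells1), "single control")
  expect_equal(nrow(ctrl1), 0)
})

test_that("null DMSO self-profiles concentrate near zero", {
  # all wells drawn from one distribution at 200 cells/well: entries rarely
  # stray; |entry| < 0.25 should hold with >= 99% frequency
  set.seed(303)
  entries <- unlist(lapply(1:6, function(r) {
    wells <- lapply(1:8, function(w) list(
      treatment = "DMSO", role = "control",
      features = matrix(rnorm(200 * 5), ncol = 5)))
    names(wells) <- paste0("D", 1:8)
    as.vector(profile_matrix(build_control_profiles(toy_cells(wells))))
  }))
  expect_gte(mean(abs(entries) < 0.25), 0.99)
})

test_that("whole-screen profiling covers compounds and controls per line", {
  cfg <- synthetic_screen_config(n_cell_lines = 2, n_features = 5,
                                 n_moas = 2, compounds_per_moa = 2,
                                 dmso_wells_per_plate = 3,
                                 cells_per_well = 30, effect_magnitude = 2,
                                 heterogeneity = 0, seed = 5)
  scr <- generate_screen(cfg)
  prof <- build_profiles(scr$cells)
  expect_equal(nrow(prof), 2 * (4 + 3))
  expect_equal(sum(prof$role == "control"), 6)
  m <- profile_matrix(prof)
  expect_true(all(m >= -1 & m <= 1))

  # per-well mode: one profile per compound well
  prof_w <- build_profiles(scr$cells, per_well = TRUE)
  expect_equal(sum(prof_w$role == "compound"), 2 * 4)
  expect_true(all(grepl("@", prof_w$treatment[prof_w$role == "compound"])))

  # CSV round trip
  p <- withr::local_tempfile(fileext = ".csv")
  write_profiles(prof, p)
  back <- read_profiles(p)
  expect_equal(feature_names(back), feature_names(prof))
  expect_equal(nrow(back), nrow(prof))
})
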