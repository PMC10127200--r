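# Shared fixtures, all built in code.

# Small per-cell table: one line, one plate, configurable wells.
# `wells` is a named list: name -> list(treatment, role, features = matrix).
toy_cells <- function(wells, cell_line = "L1", plate = "P1") {
  features <- paste0("f_", seq_len(ncol(wells[[1]]$features)))
  rows <- lapply(names(wells), function(w) {
    m <- wells[[w]]$features
    colnames(m) <- features
    dplyr::bind_cols(
      tibble::tibble(cell_line = cell_line, plate = plate, well = w,
                     treatment = wells[[w]]$treatment,
                     role = wells[[w]]$role),
      tibble::as_tibble(m))
  })
  cell_feature_table(dplyr::bind_rows(rows), features)
}

# Profile table from a matrix of profile vectors (rows = treatments).
toy_profiles <- function(mat, roles, cell_line = "L1") {
  if (is.null(rownames(mat))) {
    rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  }
  df <- tibble::tibble(cell_line = cell_line,
                       treatment = rownames(mat), role = roles)
  colnames(mat) <- paste0("f_", seq_len(ncol(mat)))
  phenotypic_profiles(dplyr::bind_cols(df, tibble::as_tibble(mat)))
}

# Direct exhaustive signed-KS oracle: ECDF difference at every sample point,
# with the same antisymmetric branch tie-break as the implementation but
# computed by brute-force mean() evaluation.
signed_ks_oracle <- function(a, b) {
  pts <- sort(c(a, b))
  d <- vapply(pts, function(x) mean(b <= x) - mean(a <= x), numeric(1))
  d_up <- max(d)
  d_dn <- max(-d)
  if (d_up > d_dn) return(d_up)
  if (d_dn > d_up) return(-d_dn)
  if (d_up == 0) return(0)
  nz <- d[d != 0]
  if (nz[1] > 0) d_up else -d_up
}

# All multisets of sizes 1..max_size over vals, as a list of sorted vectors.
all_multisets <- function(max_size, vals) {
  unlist(lapply(seq_len(max_size), function(s) {
    g <- as.matrix(do.call(expand.grid, rep(list(vals), s)))
    g <- g[!apply(g, 1, is.unsorted), , drop = FALSE]
    lapply(seq_len(nrow(g)), function(i) unname(g[i, ]))
  }), recursive = FALSE)
}

# Desk-scale screen configs used across simulation tests: a single plate per
# line, 20-feature panel -- sized so planted effects on the grid {0,1,2,4}
# span the score's dynamic range without ceiling saturation, and so the
# heterogeneity sweep runs in a dense-library regime where scattering an
# MOA's members past their local neighbor spacing is possible (see the
# methods vignette).
effect_sweep_config <- function(effect_magnitude = 0, seed = 900L, ...) {
  synthetic_screen_config(
    n_cell_lines = 1, n_features = 20, n_moas = 6, compounds_per_moa = 4,
    dmso_wells_per_plate = 8, cells_per_well = 20,
    effect_magnitude = effect_magnitude, heterogeneity = 0, seed = seed, ...)
}

tau_sweep_config <- function(heterogeneity = 0, seed = 900L, ...) {
  synthetic_screen_config(
    n_cell_lines = 1, n_features = 20, n_moas = 16, compounds_per_moa = 4,
    dmso_wells_per_plate = 8, cells_per_well = 100, effect_magnitude = 1,
    heterogeneity = heterogeneity, seed = seed, ...)
}

# planted-best-line screen: line_02 dominates with margin 2 on every MOA
best_line_config <- function(seed, n_moas = 6) {
  a <- matrix(1, n_moas, 3)
  a[, 2] <- 3
  synthetic_screen_config(
    n_cell_lines = 3, n_features = 20, n_moas = n_moas,
    compounds_per_moa = 4, dmso_wells_per_plate = 8, cells_per_well = 30,
    effect_magnitude = a, heterogeneity = 0.25, seed = seed)
}
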