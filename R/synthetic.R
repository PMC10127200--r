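#' Configuration for a synthetic multi-cell-line screen
#'
#' Defines a Gaussian cell-level generative model for a phenotypic screen with
#' planted structure. Each cell line carries per-feature baselines
#' `baseline_mu` and noise scales `baseline_sigma`; DMSO cells draw from the
#' baseline, and cells treated with compound `c` in line `l` draw from the
#' baseline shifted by the compound's effect vector
#' \deqn{v_{c,l} = a_{m(c),l} \, u_{m(c),l} + \tau_{m(c)} \, \epsilon_c,}
#' where `u` is a per-(MOA, line) unit direction, `a` (`effect_magnitude`)
#' controls phenoactivity, and `eps_c` is a per-compound latent drawn once and
#' shared across cell lines (the compound's biological identity), scaled by
#' the per-MOA heterogeneity `tau` that controls phenosimilarity.
#'
#' Because `u` has unit norm and `eps_c ~ N(0, I/D)` has unit expected squared
#' norm, both `a` and `tau` are mean displacement magnitudes in units of the
#' cell-level noise SD, comparable across feature dimensionalities.
#'
#' @param n_cell_lines Number of cell lines (default 6).
#' @param n_features Number of per-cell features D (default 77).
#' @param n_moas Number of MOA classes (default 20).
#' @param compounds_per_moa Compounds per MOA (default 5).
#' @param dmso_wells_per_plate DMSO wells on each line's plate (default 8).
#' @param wells_per_compound Replicate wells per compound (default 1).
#' @param cells_per_well Cells sampled per well (default 200).
#' @param effect_magnitude Scalar, length-`n_moas` vector, or
#'   `n_moas x n_cell_lines` matrix of planted effect magnitudes `a >= 0`.
#' @param heterogeneity Scalar or length-`n_moas` vector `tau >= 0` of
#'   within-MOA compound dispersion.
#' @param cell_noise_sd Cell-level noise SD (default 1); also the default
#'   `baseline_sigma`.
#' @param baseline_mu `NULL` (all zero), scalar, or `n_cell_lines x
#'   n_features` matrix of per-line feature baselines.
#' @param baseline_sigma `NULL` (`cell_noise_sd`), scalar, or `n_cell_lines x
#'   n_features` matrix of per-line noise scales.
#' @param cell_model `"gaussian"` (default) or `"t"` (heavy-tailed cell
#'   noise, scaled to unit SD, to stress-test KS robustness).
#' @param t_df Degrees of freedom for `cell_model = "t"` (must be > 2).
#' @param seed Integer seed; the whole screen is a deterministic function of
#'   the config.
#' @return A validated `synthetic_screen_config` list.
#' @export
synthetic_screen_config <- function(n_cell_lines = 6, n_features = 77,
                                    n_moas = 20, compounds_per_moa = 5,
                                    dmso_wells_per_plate = 8,
                                    wells_per_compound = 1,
                                    cells_per_well = 200,
                                    effect_magnitude = 1,
                                    heterogeneity = 0.25,
                                    cell_noise_sd = 1,
                                    baseline_mu = NULL,
                                    baseline_sigma = NULL,
                                    cell_model = c("gaussian", "t"),
                                    t_df = 5, seed = 1L) {
  cell_model <- match.arg(cell_model)
  check_count <- function(x, field, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
          x != floor(x)) {
      stop("invalid config field '", field, "': need an integer >= ", min,
           call. = FALSE)
    }
    as.integer(x)
  }
  n_cell_lines <- check_count(n_cell_lines, "n_cell_lines")
  n_features <- check_count(n_features, "n_features")
  n_moas <- check_count(n_moas, "n_moas")
  compounds_per_moa <- check_count(compounds_per_moa, "compounds_per_moa")
  dmso_wells_per_plate <- check_count(dmso_wells_per_plate,
                                      "dmso_wells_per_plate", min = 2)
  wells_per_compound <- check_count(wells_per_compound, "wells_per_compound")
  cells_per_well <- check_count(cells_per_well, "cells_per_well")
  seed <- check_count(seed, "seed", min = 0)

  a <- effect_magnitude
  if (is.matrix(a)) {
    if (!all(dim(a) == c(n_moas, n_cell_lines))) {
      stop("invalid config field 'effect_magnitude': matrix must be ",
           n_moas, " x ", n_cell_lines, call. = FALSE)
    }
  } else if (length(a) == 1) {
    a <- matrix(a, n_moas, n_cell_lines)
  } else if (length(a) == n_moas) {
    a <- matrix(a, n_moas, n_cell_lines)
  } else {
    stop("invalid config field 'effect_magnitude': scalar, length-n_moas ",
         "vector, or n_moas x n_cell_lines matrix", call. = FALSE)
  }
  if (any(is.na(a)) || any(a < 0)) {
    stop("invalid config field 'effect_magnitude': values must be >= 0",
         call. = FALSE)
  }
  tau <- heterogeneity
  if (length(tau) == 1) tau <- rep(tau, n_moas)
  if (length(tau) != n_moas || any(is.na(tau)) || any(tau < 0)) {
    stop("invalid config field 'heterogeneity': scalar or length-n_moas, ",
         "values >= 0", call. = FALSE)
  }
  if (!is.numeric(cell_noise_sd) || cell_noise_sd <= 0) {
    stop("invalid config field 'cell_noise_sd': need a positive number",
         call. = FALSE)
  }
  expand_line_feature <- function(x, field, default) {
    if (is.null(x)) x <- default
    if (is.matrix(x)) {
      if (!all(dim(x) == c(n_cell_lines, n_features))) {
        stop("invalid config field '", field, "': matrix must be ",
             n_cell_lines, " x ", n_features, call. = FALSE)
      }
      x
    } else if (length(x) == 1) {
      matrix(x, n_cell_lines, n_features)
    } else {
      stop("invalid config field '", field, "': scalar or n_cell_lines x ",
           "n_features matrix", call. = FALSE)
    }
  }
  baseline_mu <- expand_line_feature(baseline_mu, "baseline_mu", 0)
  baseline_sigma <- expand_line_feature(baseline_sigma, "baseline_sigma",
                                        cell_noise_sd)
  if (any(baseline_sigma <= 0)) {
    stop("invalid config field 'baseline_sigma': values must be > 0",
         call. = FALSE)
  }
  if (cell_model == "t" && (!is.numeric(t_df) || t_df <= 2)) {
    stop("invalid config field 't_df': need > 2 for finite variance",
         call. = FALSE)
  }
  structure(
    list(n_cell_lines = n_cell_lines, n_features = n_features,
         n_moas = n_moas, compounds_per_moa = compounds_per_moa,
         dmso_wells_per_plate = dmso_wells_per_plate,
         wells_per_compound = wells_per_compound,
         cells_per_well = cells_per_well,
         effect_magnitude = a, heterogeneity = tau,
         cell_noise_sd = cell_noise_sd, baseline_mu = baseline_mu,
         baseline_sigma = baseline_sigma, cell_model = cell_model,
         t_df = t_df, seed = seed),
    class = "synthetic_screen_config"
  )
}

#' Generate a synthetic screen with planted ground truth
#'
#' Draws, in a fixed order under the config's seed: per-(MOA, line) unit
#' effect directions `u`, per-compound heterogeneity latents `eps`, then the
#' per-cell feature values line by line (DMSO wells first, then compound
#' wells). Identical configs produce identical screens.
#'
#' @param cfg A [synthetic_screen_config()].
#' @return A list with `cells` (a [cell_feature_table()] over all lines),
#'   `annotation` (a [moa_annotation()]), and `truth` (list with the drawn
#'   `u`, `eps`, the effect vectors `v[compound, line, feature]`, and the
#'   planted `effect_magnitude` / `heterogeneity`).
#' @export
generate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_screen_config"))
  set.seed(cfg$seed)
  D <- cfg$n_features
  lines <- sprintf("line_%02d", seq_len(cfg$n_cell_lines))
  moas <- sprintf("moa_%02d", seq_len(cfg$n_moas))
  compounds <- as.vector(t(outer(moas, seq_len(cfg$compounds_per_moa),
                                 function(m, j) sprintf("%s_c%02d", m, j))))
  moa_of <- rep(moas, each = cfg$compounds_per_moa)
  features <- paste0("f_", seq_len(D))

  u <- array(0, dim = c(cfg$n_moas, cfg$n_cell_lines, D))
  for (m in seq_len(cfg$n_moas)) {
    for (l in seq_len(cfg$n_cell_lines)) {
      z <- stats::rnorm(D)
      u[m, l, ] <- z / sqrt(sum(z^2))
    }
  }
  eps <- matrix(stats::rnorm(length(compounds) * D, sd = 1 / sqrt(D)),
                nrow = length(compounds), ncol = D,
                dimnames = list(compounds, features))
  v <- array(0, dim = c(length(compounds), cfg$n_cell_lines, D),
             dimnames = list(compounds, lines, features))
  for (ci in seq_along(compounds)) {
    m <- match(moa_of[ci], moas)
    for (l in seq_len(cfg$n_cell_lines)) {
      v[ci, l, ] <- cfg$effect_magnitude[m, l] * u[m, l, ] +
        cfg$heterogeneity[m] * eps[ci, ]
    }
  }

  draw_noise <- function(n) {
    if (cfg$cell_model == "gaussian") {
      stats::rnorm(n)
    } else {
      stats::rt(n, df = cfg$t_df) / sqrt(cfg$t_df / (cfg$t_df - 2))
    }
  }
  nc <- cfg$cells_per_well
  tables <- vector("list", cfg$n_cell_lines)
  for (l in seq_len(cfg$n_cell_lines)) {
    plate <- paste0(lines[l], "_P1")
    mu_l <- cfg$baseline_mu[l, ]
    sd_l <- cfg$baseline_sigma[l, ]
    blocks <- list()
    for (w in seq_len(cfg$dmso_wells_per_plate)) {
      x <- matrix(draw_noise(nc * D), nrow = nc, ncol = D)
      x <- sweep(sweep(x, 2, sd_l, `*`), 2, mu_l, `+`)
      colnames(x) <- features
      blocks[[length(blocks) + 1]] <- dplyr::bind_cols(
        tibble::tibble(cell_line = lines[l], plate = plate,
                       well = sprintf("D%02d", w), treatment = "DMSO",
                       role = "control"),
        tibble::as_tibble(x))
    }
    for (ci in seq_along(compounds)) {
      for (w in seq_len(cfg$wells_per_compound)) {
        x <- matrix(draw_noise(nc * D), nrow = nc, ncol = D)
        x <- sweep(sweep(x, 2, sd_l, `*`), 2, mu_l + v[ci, l, ], `+`)
        colnames(x) <- features
        blocks[[length(blocks) + 1]] <- dplyr::bind_cols(
          tibble::tibble(cell_line = lines[l], plate = plate,
                         well = sprintf("C%03d_%d", ci, w),
                         treatment = compounds[ci], role = "compound"),
          tibble::as_tibble(x))
      }
    }
    tables[[l]] <- dplyr::bind_rows(blocks)
  }
  cells <- cell_feature_table(dplyr::bind_rows(tables), features)
  annotation <- moa_annotation(tibble::tibble(compound = compounds,
                                              moa = moa_of))
  list(cells = cells, annotation = annotation,
       truth = list(u = u, eps = eps, v = v,
                    effect_magnitude = cfg$effect_magnitude,
                    heterogeneity = cfg$heterogeneity,
                    lines = lines, moas = moas, compounds = compounds))
}

#' Parameter-recovery report for the scoring definitions
#'
#' Sweeps the planted effect magnitude `a` and/or the within-MOA
#' heterogeneity `tau` over a grid, regenerating and re-scoring the screen
#' for several seeds per grid point, and summarizes the monotone trends:
#' mean phenoactivity is expected to increase with `a` and mean
#' phenosimilarity to decrease with `tau` (Spearman correlation of the grid
#' means, +1 / -1 when the trend is strict).
#'
#' The same per-replicate seeds (`cfg$seed + 1, ..., cfg$seed + n_seeds`) are
#' reused at every grid point, so grid points differ only in the swept
#' parameter.
#'
#' @param base_cfg A [synthetic_screen_config()] providing every non-swept
#'   parameter.
#' @param effect_grid Numeric grid of `a` values (>= 2 values), or `NULL` to
#'   skip the effect sweep.
#' @param heterogeneity_grid Numeric grid of `tau` values (>= 2 values), or
#'   `NULL` to skip.
#' @param n_seeds Replicate screens per grid point (default 10).
#' @return A list: `results` (tibble with one row per sweep x value x seed,
#'   columns `mean_phenoactivity` and `mean_phenosimilarity`), `grid_means`
#'   (per sweep x value means over seeds), and `summary` (one row per sweep
#'   with the Spearman correlation of the relevant grid means).
#' @export
parameter_recovery_report <- function(base_cfg, effect_grid = NULL,
                                      heterogeneity_grid = NULL,
                                      n_seeds = 10) {
  stopifnot(inherits(base_cfg, "synthetic_screen_config"))
  if (is.null(effect_grid) && is.null(heterogeneity_grid)) {
    stop("provide at least one of effect_grid, heterogeneity_grid",
         call. = FALSE)
  }
  for (g in list(effect = effect_grid, heterogeneity = heterogeneity_grid)) {
    if (!is.null(g) && length(unique(g)) < 2) {
      stop("degenerate grid: need >= 2 distinct values per swept parameter",
           call. = FALSE)
    }
  }
  if (n_seeds < 1) stop("n_seeds must be >= 1", call. = FALSE)

  eval_point <- function(cfg) {
    screen <- generate_screen(cfg)
    profiles <- build_profiles(screen$cells)
    pa <- score_all_phenoactivity(profiles, screen$annotation,
                                  min_moa_size = 1)
    ps <- suppressWarnings(
      score_all_phenosimilarity(profiles, screen$annotation,
                                min_moa_size = 2))
    c(mean_phenoactivity = mean(pa$score),
      mean_phenosimilarity = mean(ps$score))
  }
  sweep_one <- function(sweep_name, grid) {
    dplyr::bind_rows(lapply(grid, function(val) {
      dplyr::bind_rows(lapply(seq_len(n_seeds), function(s) {
        args <- unclass(base_cfg)
        if (sweep_name == "effect") args$effect_magnitude <- val
        if (sweep_name == "heterogeneity") args$heterogeneity <- val
        args$seed <- base_cfg$seed + s
        res <- eval_point(do.call(synthetic_screen_config, args))
        tibble::tibble(sweep = sweep_name, value = val, seed = args$seed,
                       mean_phenoactivity = res[["mean_phenoactivity"]],
                       mean_phenosimilarity = res[["mean_phenosimilarity"]])
      }))
    }))
  }
  results <- dplyr::bind_rows(
    if (!is.null(effect_grid)) sweep_one("effect", effect_grid),
    if (!is.null(heterogeneity_grid)) sweep_one("heterogeneity",
                                                heterogeneity_grid))
  grid_means <- dplyr::summarise(
    dplyr::group_by(results, .data$sweep, .data$value),
    mean_phenoactivity = mean(.data$mean_phenoactivity),
    mean_phenosimilarity = mean(.data$mean_phenosimilarity),
    .groups = "drop")
  summary <- dplyr::bind_rows(lapply(split(grid_means, grid_means$sweep),
                                     function(g) {
    tibble::tibble(
      sweep = g$sweep[1],
      spearman_phenoactivity = stats::cor(g$value, g$mean_phenoactivity,
                                          method = "spearman"),
      spearman_phenosimilarity = stats::cor(g$value, g$mean_phenosimilarity,
                                            method = "spearman"))
  }))
  list(results = results, grid_means = grid_means, summary = summary)
}
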