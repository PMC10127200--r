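#' Signed two-sample Kolmogorov-Smirnov statistic
#'
#' The magnitude is the classical two-sample KS statistic
#' \eqn{D = \sup_x |F_{treated}(x) - F_{control}(x)|}; the sign encodes the
#' direction of the dominant ECDF branch: positive when the treated sample is
#' stochastically larger (its ECDF runs below the control ECDF), negative
#' otherwise. When the two branches tie exactly, the sign is taken from the
#' first nonzero ECDF difference along the sorted pooled sample points; this
#' tie-break is deterministic and keeps the statistic exactly antisymmetric
#' (swapping the samples negates every ECDF difference).
#'
#' @param treated,control Non-empty numeric samples.
#' @return A scalar in \[-1, 1\].
#' @examples
#' signed_ks(c(10, 11, 12), c(1, 2, 3)) # +1: complete upward separation
#' signed_ks(c(1, 3), c(2, 4))          # -0.5
#' @export
signed_ks <- function(treated, control) {
  if (length(treated) == 0) stop("'treated' sample is empty", call. = FALSE)
  if (length(control) == 0) stop("'control' sample is empty", call. = FALSE)
  if (anyNA(treated) || anyNA(control)) {
    stop("signed_ks: samples must not contain NA", call. = FALSE)
  }
  x <- sort(unique(c(treated, control)))
  diffs <- findInterval(x, sort(control)) / length(control) -
    findInterval(x, sort(treated)) / length(treated)  # F_c - F_t
  d_up <- max(diffs)   # treated shifted upward
  d_dn <- max(-diffs)  # treated shifted downward
  if (d_up > d_dn) return(d_up)
  if (d_dn > d_up) return(-d_dn)
  if (d_up == 0) return(0)
  nz <- diffs[diffs != 0]
  if (nz[1] > 0) d_up else -d_up
}

# sup_x [F_a(x) - F_b(x)], the one-sided ECDF supremum used by both score
# functionals; the sup of two right-continuous step functions is attained at
# a pooled sample point.
ecdf_sup_diff <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("ecdf_sup_diff: empty sample", call. = FALSE)
  }
  x <- sort(unique(c(a, b)))
  max(findInterval(x, sort(a)) / length(a) -
        findInterval(x, sort(b)) / length(b))
}

profile_meta_cols <- c("cell_line", "treatment", "role",
                       "n_cells_treated", "n_cells_control")

new_profiles <- function(df, features) {
  df <- tibble::as_tibble(df)
  structure(df, features = features,
            class = c("phenotypic_profiles", class(df)))
}

#' Construct a phenotypic profile table
#'
#' Validating constructor for profile tables built elsewhere (e.g. planted
#' toy configurations in analyses): one row per profile with metadata columns
#' `cell_line`, `treatment`, `role` (plus optional cell counts) and one
#' signed-KS value per feature, each in \[-1, 1\].
#'
#' @param df Data frame of profiles.
#' @param features Feature column names; default: every non-metadata column.
#' @return A `phenotypic_profiles` tibble.
#' @export
phenotypic_profiles <- function(df, features = NULL) {
  df <- tibble::as_tibble(df)
  need <- setdiff(c("cell_line", "treatment", "role"), names(df))
  if (length(need) > 0) {
    stop("profile table lacks column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"n_cells_treated" %in% names(df)) df$n_cells_treated <- NA_integer_
  if (!"n_cells_control" %in% names(df)) df$n_cells_control <- NA_integer_
  features <- features %||% setdiff(names(df), profile_meta_cols)
  if (length(features) == 0) stop("no feature columns", call. = FALSE)
  for (fc in features) {
    if (!is.numeric(df[[fc]]) || anyNA(df[[fc]]) ||
          any(df[[fc]] < -1 | df[[fc]] > 1)) {
      stop("profile entries must be signed-KS values in [-1, 1]; column '",
           fc, "' is not", call. = FALSE)
    }
  }
  bad_role <- setdiff(unique(df$role), c("compound", "control"))
  if (length(bad_role) > 0) {
    stop("profile role must be 'compound' or 'control'", call. = FALSE)
  }
  new_profiles(df[, c(profile_meta_cols, features)], features)
}

# control cells matched to a set of plates under the pooling policy
matched_controls <- function(cells, plates, control_policy) {
  ctrl <- cells[cells$role == "control", , drop = FALSE]
  if (control_policy == "plate") {
    ctrl <- ctrl[ctrl$plate %in% plates, , drop = FALSE]
  }
  ctrl
}

#' Build the phenotypic profile of one treatment in one cell line
#'
#' Pools the treatment's cells across its replicate wells and computes, per
#' feature, the signed KS statistic of treated cells against matched DMSO
#' control cells. Under the default `"plate"` policy the controls are all
#' control cells on the plate(s) carrying the treatment's wells; `"global"`
#' pools controls across all plates of the cell line.
#'
#' @param cells A [cell_feature_table()] restricted to one cell line.
#' @param treatment Treatment (compound) identifier present in `cells`.
#' @param control_policy `"plate"` (default) or `"global"` control pooling.
#' @return A one-row `phenotypic_profiles` tibble: metadata plus one signed-KS
#'   value per feature.
#' @export
build_profile <- function(cells, treatment,
                          control_policy = c("plate", "global")) {
  control_policy <- match.arg(control_policy)
  features <- feature_names(cells)
  line <- unique(cells$cell_line)
  if (length(line) != 1) {
    stop("build_profile expects cells from a single cell line; got: ",
         paste(line, collapse = ", "), call. = FALSE)
  }
  treated <- cells[cells$treatment == treatment & cells$role == "compound", ,
                   drop = FALSE]
  if (nrow(treated) == 0) {
    stop("no treated cells for treatment '", treatment, "'", call. = FALSE)
  }
  plates <- unique(treated$plate)
  ctrl <- matched_controls(cells, plates, control_policy)
  if (nrow(ctrl) == 0) {
    stop("no control cells on plate(s) ", paste(plates, collapse = ", "),
         " for treatment '", treatment, "'", call. = FALSE)
  }
  vec <- vapply(features, function(fc) signed_ks(treated[[fc]], ctrl[[fc]]),
                numeric(1))
  row <- tibble::tibble(cell_line = line, treatment = treatment,
                        role = "compound",
                        n_cells_treated = nrow(treated),
                        n_cells_control = nrow(ctrl))
  row[features] <- as.list(vec)
  new_profiles(row, features)
}

#' Build leave-one-well-out DMSO self-profiles
#'
#' The DMSO condition must itself form a nondegenerate point cloud in profile
#' space (its centroid and distance spread anchor the phenoactivity score).
#' Each control well is profiled against all *other* control cells on the same
#' plate, so that sampling noise — not a tautological zero — sets the cloud's
#' scale. Plates with a single control well cannot be profiled this way and
#' are skipped with a warning.
#'
#' @param cells A [cell_feature_table()] restricted to one cell line.
#' @param control_policy `"plate"` (default) or `"global"`: whether the
#'   leave-one-out reference pools control cells within the well's plate or
#'   across all plates.
#' @return A `phenotypic_profiles` tibble, one row per control well, with
#'   role `"control"` and treatment `"<plate>:<well>"`.
#' @export
build_control_profiles <- function(cells,
                                   control_policy = c("plate", "global")) {
  control_policy <- match.arg(control_policy)
  features <- feature_names(cells)
  line <- unique(cells$cell_line)
  if (length(line) != 1) {
    stop("build_control_profiles expects cells from a single cell line",
         call. = FALSE)
  }
  ctrl <- cells[cells$role == "control", , drop = FALSE]
  wells <- unique(ctrl[, c("plate", "well")])
  rows <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    pl <- wells$plate[i]; wl <- wells$well[i]
    held <- ctrl[ctrl$plate == pl & ctrl$well == wl, , drop = FALSE]
    rest <- if (control_policy == "plate") {
      ctrl[ctrl$plate == pl & ctrl$well != wl, , drop = FALSE]
    } else {
      ctrl[!(ctrl$plate == pl & ctrl$well == wl), , drop = FALSE]
    }
    if (nrow(rest) == 0) {
      warning("plate '", pl, "' has a single control well; well '", wl,
              "' skipped", call. = FALSE)
      next
    }
    vec <- vapply(features, function(fc) signed_ks(held[[fc]], rest[[fc]]),
                  numeric(1))
    row <- tibble::tibble(cell_line = line,
                          treatment = paste(pl, wl, sep = ":"),
                          role = "control",
                          n_cells_treated = nrow(held),
                          n_cells_control = nrow(rest))
    row[features] <- as.list(vec)
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    empty <- tibble::tibble(cell_line = character(), treatment = character(),
                            role = character(), n_cells_treated = integer(),
                            n_cells_control = integer())
    empty[features] <- lapply(features, function(f) numeric(0))
    return(new_profiles(empty, features))
  }
  new_profiles(dplyr::bind_rows(rows), features)
}

#' Profile a whole screen
#'
#' Builds, for every cell line in the table, one pooled profile per compound
#' and the leave-one-well-out DMSO self-profiles. With `per_well = TRUE`
#' compound profiles are built per well instead of pooled across replicate
#' wells (the pooled mode matches one-point-per-compound profile clouds).
#'
#' @param cells A [cell_feature_table()] covering one or more cell lines.
#' @param control_policy Control pooling policy, see [build_profile()].
#' @param per_well Build one profile per (compound, well) instead of pooling
#'   replicate wells.
#' @return A `phenotypic_profiles` tibble with compound and control rows for
#'   every cell line.
#' @export
build_profiles <- function(cells, control_policy = c("plate", "global"),
                           per_well = FALSE) {
  control_policy <- match.arg(control_policy)
  features <- feature_names(cells)
  per_line <- split(seq_len(nrow(cells)), cells$cell_line)
  out <- lapply(per_line, function(idx) {
    sub <- cell_feature_table(cells[idx, , drop = FALSE], features)
    compounds <- sort(unique(sub$treatment[sub$role == "compound"]))
    cmpd_rows <- lapply(compounds, function(tr) {
      if (!per_well) return(build_profile(sub, tr, control_policy))
      trt <- sub[sub$treatment == tr & sub$role == "compound", , drop = FALSE]
      wells <- unique(trt[, c("plate", "well")])
      dplyr::bind_rows(lapply(seq_len(nrow(wells)), function(i) {
        one <- sub[sub$role == "control" |
                     (sub$treatment == tr & sub$plate == wells$plate[i] &
                        sub$well == wells$well[i]), , drop = FALSE]
        p <- build_profile(cell_feature_table(one, features), tr,
                           control_policy)
        p$treatment <- paste(tr, wells$plate[i], wells$well[i], sep = "@")
        p
      }))
    })
    dplyr::bind_rows(c(cmpd_rows,
                       list(build_control_profiles(sub, control_policy))))
  })
  new_profiles(dplyr::bind_rows(out), features)
}

#' Extract the profile matrix from a profile table
#'
#' @param profiles A `phenotypic_profiles` tibble.
#' @param role Optional filter: `"compound"` or `"control"`.
#' @return A numeric matrix, rows named by treatment identifier.
#' @export
profile_matrix <- function(profiles, role = NULL) {
  features <- feature_names(profiles)
  if (!is.null(role)) {
    profiles <- profiles[profiles$role == role, , drop = FALSE]
  }
  m <- as.matrix(profiles[, features, drop = FALSE])
  rownames(m) <- profiles$treatment
  m
}

#' Write / read profile tables
#'
#' Profiles round-trip through CSV with the layout
#' `cell_line,treatment,role,n_cells_treated,n_cells_control,f_1..f_D`.
#'
#' @param profiles A `phenotypic_profiles` tibble.
#' @param path CSV path.
#' @return `write_profiles`: `path` invisibly; `read_profiles`: the profile
#'   table.
#' @export
write_profiles <- function(profiles, path) {
  ord <- order(profiles$cell_line, profiles$role, profiles$treatment,
               method = "radix")
  readr::write_csv(profiles[ord, , drop = FALSE], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  new_profiles(df, setdiff(names(df), profile_meta_cols))
}
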