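#' Column schema for per-cell feature tables
#'
#' Maps the canonical metadata roles (cell line, plate, well, treatment, role)
#' to whatever the input file calls them, and says which columns hold the
#' per-cell features. Arbitrary feature panels are accepted: features can be
#' named explicitly or matched by a regular expression (default `^f_`, the
#' naming used by [generate_screen()]).
#'
#' @param cell_line,plate,well,treatment,role Names of the metadata columns in
#'   the input file.
#' @param features Character vector of feature column names, or `NULL` to match
#'   by `feature_regex`.
#' @param feature_regex Regular expression selecting feature columns when
#'   `features` is `NULL`.
#' @param control_label Value of the treatment column marking vehicle-control
#'   (DMSO) wells; rows with this treatment get role `"control"`, all others
#'   `"compound"`, when the file has no role column of its own.
#' @return A list with class `screen_schema`.
#' @export
screen_schema <- function(cell_line = "cell_line", plate = "plate",
                          well = "well", treatment = "treatment",
                          role = "role", features = NULL,
                          feature_regex = "^f_", control_label = "DMSO") {
  structure(
    list(cell_line = cell_line, plate = plate, well = well,
         treatment = treatment, role = role, features = features,
         feature_regex = feature_regex, control_label = control_label),
    class = "screen_schema"
  )
}

metadata_cols <- c("cell_line", "plate", "well", "treatment", "role")

#' Construct and validate a per-cell feature table
#'
#' The central input container: one row per segmented cell, with metadata
#' columns `cell_line`, `plate`, `well`, `treatment`, `role` and numeric
#' feature columns. Validation enforces the container's invariants: complete
#' numeric features, roles in `{compound, control}`, and at least one control
#' well on every plate that carries a compound well.
#'
#' @param df A data frame holding metadata and feature columns.
#' @param features Character vector naming the feature columns.
#' @return A `cell_feature_table` (a tibble with a `features` attribute).
#' @export
cell_feature_table <- function(df, features) {
  df <- tibble::as_tibble(df)
  missing_meta <- setdiff(metadata_cols, names(df))
  if (length(missing_meta) > 0) {
    stop("missing mandatory metadata column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  if (length(features) == 0) {
    stop("no feature columns identified", call. = FALSE)
  }
  absent <- setdiff(features, names(df))
  if (length(absent) > 0) {
    stop("feature column(s) not present: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  for (fc in features) {
    if (!is.numeric(df[[fc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[fc]]))) &
                     !is.na(df[[fc]]))
      stop("non-numeric value in feature column '", fc, "' at row ",
           if (length(bad)) bad[1] else NA_integer_, call. = FALSE)
    }
    if (anyNA(df[[fc]])) {
      stop("missing values remain in feature column '", fc,
           "'; apply the row-drop policy first (see read_cell_table)",
           call. = FALSE)
    }
  }
  bad_role <- setdiff(unique(df$role), c("compound", "control"))
  if (length(bad_role) > 0) {
    stop("role must be 'compound' or 'control'; found: ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  }
  cmpd_plates <- unique(df$plate[df$role == "compound"])
  ctrl_plates <- unique(df$plate[df$role == "control"])
  orphans <- setdiff(cmpd_plates, ctrl_plates)
  if (length(orphans) > 0) {
    stop("plate(s) with compound wells but no control wells: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  df <- df[, c(metadata_cols, features)]
  structure(df, features = features,
            class = c("cell_feature_table", class(df)))
}

#' Feature column names of a table or profile set
#'
#' @param x A `cell_feature_table` or `phenotypic_profiles` object.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(x) attr(x, "features", exact = TRUE)

#' Read a per-cell feature table from CSV
#'
#' Reads a delimited per-cell table, renames columns to the canonical schema,
#' and applies the row-drop policy: any cell (row) with a missing feature value
#' is dropped — never imputed — and the number of dropped rows is reported and
#' stored in the `n_dropped` attribute. Profiling then operates on observed
#' cells only, which is all a rank-based statistic needs.
#'
#' If the file has no role column, roles are derived from the treatment column
#' using `schema$control_label`.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [screen_schema()] describing the file's columns.
#' @return A [cell_feature_table()]; attribute `n_dropped` counts removed rows.
#' @export
read_cell_table <- function(path, schema = screen_schema()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (m in setdiff(metadata_cols, "role")) {
    src <- schema[[m]]
    if (!src %in% names(raw)) {
      stop("input file lacks mandatory metadata column '", src,
           "' (schema role: ", m, ")", call. = FALSE)
    }
    names(raw)[names(raw) == src] <- m
  }
  if (schema$role %in% names(raw)) {
    names(raw)[names(raw) == schema$role] <- "role"
  } else {
    raw$role <- ifelse(raw$treatment == schema$control_label,
                       "control", "compound")
  }
  features <- schema$features %||%
    grep(schema$feature_regex, names(raw), value = TRUE)
  if (length(features) == 0) {
    stop("no feature columns matched by schema (regex '",
         schema$feature_regex, "')", call. = FALSE)
  }
  for (fc in features) {
    if (!is.numeric(raw[[fc]])) {
      suppressWarnings(num <- as.numeric(raw[[fc]]))
      bad <- which(is.na(num) & !is.na(raw[[fc]]) & raw[[fc]] != "NA")
      if (length(bad) > 0) {
        stop("non-numeric value '", raw[[fc]][bad[1]],
             "' in feature column '", fc, "' at row ", bad[1], call. = FALSE)
      }
      raw[[fc]] <- num
    }
  }
  complete <- stats::complete.cases(raw[, features])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped for missing feature values")
  }
  out <- cell_feature_table(raw[complete, , drop = FALSE], features)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read compound-to-MOA annotations
#'
#' Reads a two-column table mapping compound identifiers to
#' mechanism-of-action (MOA) class labels. A compound annotated with several
#' MOAs appears on several rows and contributes its profile to each of those
#' MOA point clouds downstream. Exact duplicate rows are removed with a
#' warning; empty labels are an error.
#'
#' @param path Path to a CSV with columns `compound` and `moa`.
#' @return A tibble with columns `compound` and `moa` (class
#'   `moa_annotation`).
#' @export
read_annotations <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  moa_annotation(raw)
}

#' Validate a compound-to-MOA annotation table
#'
#' @param df Data frame with columns `compound` and `moa`.
#' @return A validated `moa_annotation` tibble.
#' @export
moa_annotation <- function(df) {
  df <- tibble::as_tibble(df)
  need <- setdiff(c("compound", "moa"), names(df))
  if (length(need) > 0) {
    stop("annotation table lacks column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$compound <- as.character(df$compound)
  df$moa <- as.character(df$moa)
  if (any(is.na(df$moa) | !nzchar(trimws(df$moa)))) {
    stop("empty MOA label in annotation table", call. = FALSE)
  }
  if (any(is.na(df$compound) | !nzchar(trimws(df$compound)))) {
    stop("empty compound identifier in annotation table", call. = FALSE)
  }
  dup <- duplicated(df[, c("compound", "moa")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (compound, moa) row(s) removed",
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[, c("compound", "moa")]
  class(df) <- c("moa_annotation", class(df))
  df
}

#' Write a score table to CSV
#'
#' Rows are written in deterministic order (cell line, then MOA,
#' lexicographic) so that output files are byte-stable across runs, and a
#' read-back with [read_scores()] reproduces the table.
#'
#' @param scores A score table, as produced by [score_all_phenoactivity()] or
#'   [score_all_phenosimilarity()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  need <- setdiff(c("cell_line", "moa", "n_compounds", "score"), names(scores))
  if (length(need) > 0) {
    stop("score table lacks column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(scores$cell_line, scores$moa, method = "radix")
  readr::write_csv(scores[ord, , drop = FALSE], path, progress = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path CSV path.
#' @return A tibble of scores.
#' @export
read_scores <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a run configuration file
#'
#' A single YAML file can carry input paths, the column schema and analysis
#' parameters for a whole run. The `schema` section, when present, is turned
#' into a [screen_schema()].
#'
#' @param path Path to a YAML configuration file.
#' @return A named list; element `schema` is a `screen_schema` when configured.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$schema)) {
    cfg$schema <- do.call(screen_schema, cfg$schema)
  }
  cfg
}
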