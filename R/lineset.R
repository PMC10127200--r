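#' Max-aggregate per-MOA scores over a set of cell lines
#'
#' A cell-line set detects an MOA as well as its best member does: the set's
#' per-MOA score is the maximum single-line score. Only MOAs scored in every
#' chosen line are eligible, so that sets are compared on a common MOA panel.
#'
#' @param scores Combined score table over cell lines (columns `cell_line`,
#'   `moa`, `score`), as from [score_all_phenoactivity()] or
#'   [score_all_phenosimilarity()].
#' @param lines Character vector of cell-line identifiers.
#' @return A tibble with columns `moa` and `score` (the per-MOA max).
#' @export
aggregate_set <- function(scores, lines) {
  missing_lines <- setdiff(lines, unique(scores$cell_line))
  if (length(missing_lines) > 0) {
    stop("no scores for cell line(s): ",
         paste(missing_lines, collapse = ", "), call. = FALSE)
  }
  sub <- scores[scores$cell_line %in% lines, , drop = FALSE]
  counts <- table(sub$moa)
  eligible <- names(counts)[counts == length(lines)]
  sub <- sub[sub$moa %in% eligible, , drop = FALSE]
  out <- dplyr::summarise(dplyr::group_by(sub, .data$moa),
                          score = max(.data$score), .groups = "drop")
  dplyr::arrange(out, .data$moa)
}

#' Summarize per-MOA scores into one panel-level number
#'
#' @param per_moa_score Numeric vector of per-MOA scores, or the tibble
#'   returned by [aggregate_set()].
#' @param method `"mean"` (default) or `"median"`.
#' @return A scalar in \[0, 1\].
#' @export
summarize_scores <- function(per_moa_score, method = c("mean", "median")) {
  method <- match.arg(method)
  x <- if (is.data.frame(per_moa_score)) per_moa_score$score
       else per_moa_score
  if (length(x) == 0) stop("no eligible MOA scores to summarize",
                           call. = FALSE)
  if (method == "mean") mean(x) else stats::median(x)
}

#' Relative improvement between two panel summaries
#'
#' @param base_summary Reference summary score (> 0), e.g. the best single
#'   line.
#' @param set_summary Summary score of the candidate set.
#' @return Percent change, `100 * (set - base) / base`.
#' @examples
#' improvement(0.576, 0.611) # ~6.1 percent
#' @export
improvement <- function(base_summary, set_summary) {
  if (any(base_summary <= 0)) {
    stop("improvement undefined for non-positive base summary", call. = FALSE)
  }
  100 * (set_summary - base_summary) / base_summary
}

# one combined score table for a task, warnings muffled for resampling loops
score_screen <- function(profiles, annotation, task, min_moa_size,
                         quiet = FALSE, ...) {
  run <- function() {
    switch(task,
           phenoactivity =
             score_all_phenoactivity(profiles, annotation,
                                     min_moa_size = min_moa_size, ...),
           phenosimilarity =
             score_all_phenosimilarity(profiles, annotation,
                                       min_moa_size = min_moa_size, ...))
  }
  if (quiet) suppressWarnings(run()) else run()
}

subset_compounds <- function(profiles, keep) {
  idx <- profiles$role != "compound" | profiles$treatment %in% keep
  new_profiles(profiles[idx, , drop = FALSE], feature_names(profiles))
}

#' Panel summaries under compound subsampling
#'
#' Robustness of a panel summary to the composition of the compound library:
#' each draw samples `floor(fraction * N)` of the profiled compounds without
#' replacement, re-scores every cell line on the reduced library, and
#' re-summarizes each candidate set. MOAs falling below the size filter
#' within a draw drop out of that draw (never an error); a draw with no
#' eligible MOA for a set yields `NA`.
#'
#' Per-draw seeds are `seed + draw`, so a run is reproducible from the single
#' global seed.
#'
#' @param profiles,annotation As in [rank_sets()].
#' @param task `"phenoactivity"` or `"phenosimilarity"`.
#' @param sets List of character vectors of cell-line identifiers.
#' @param n_draws Number of subsample draws (default 50).
#' @param fraction Fraction of compounds retained per draw (default 2/3).
#' @param seed Global seed governing all draws.
#' @param min_moa_size MOA size filter applied within each draw.
#' @param ... Passed to the task's scoring function.
#' @return A numeric matrix, `n_draws` rows by `length(sets)` columns, of
#'   per-draw summaries.
#' @export
subsample_summaries <- function(profiles, annotation, task, sets,
                                n_draws = 50, fraction = 2 / 3, seed = 1L,
                                min_moa_size = 5, ...) {
  stopifnot(n_draws >= 1, fraction > 0, fraction <= 1)
  compounds <- sort(unique(profiles$treatment[profiles$role == "compound"]))
  n_keep <- floor(fraction * length(compounds))
  out <- matrix(NA_real_, nrow = n_draws, ncol = length(sets),
                dimnames = list(NULL, vapply(sets, paste, "",
                                             collapse = ";")))
  for (i in seq_len(n_draws)) {
    set.seed(seed + i)
    keep <- sample(compounds, n_keep)
    sub <- subset_compounds(profiles, keep)
    scores <- tryCatch(
      score_screen(sub, annotation, task, min_moa_size, quiet = TRUE, ...),
      error = function(e) NULL)
    if (is.null(scores)) next
    for (j in seq_along(sets)) {
      per_moa <- tryCatch(aggregate_set(scores, sets[[j]]),
                          error = function(e) NULL)
      if (is.null(per_moa) || nrow(per_moa) == 0) {
        message("draw ", i, ": no eligible MOA for set ",
                paste(sets[[j]], collapse = ";"))
        next
      }
      out[i, j] <- summarize_scores(per_moa)
    }
  }
  out
}

#' Rank cell-line sets by max-aggregated panel summaries
#'
#' Enumerates every subset of the profiled cell lines up to `max_set_size`
#' (exhaustive — with the half-dozen lines of a typical panel this is at most
#' 63 sets), scores each by the mean of per-MOA max-aggregated scores, and
#' optionally attaches a compound-subsampling distribution per set. Ordering
#' is total: summary descending, then fewer lines, then lexicographic line
#' names.
#'
#' @param profiles A `phenotypic_profiles` tibble over >= 1 cell line.
#' @param annotation A [moa_annotation()] table.
#' @param task `"phenoactivity"` or `"phenosimilarity"`.
#' @param max_set_size Largest set size to enumerate.
#' @param min_moa_size MOA size filter (default 5, the reporting filter).
#' @param n_draws Subsample draws per set (0 = none).
#' @param fraction,seed See [subsample_summaries()].
#' @param summary_stat `"mean"` (default) or `"median"` over MOAs.
#' @param ... Passed to the task's scoring function.
#' @return A tibble ordered best-first: `lines` (semicolon-joined), `task`,
#'   `n_lines`, `n_moas`, `summary`, and with draws also `subsample_mean`,
#'   `subsample_sd` and the list column `subsample_summaries`.
#' @export
rank_sets <- function(profiles, annotation,
                      task = c("phenoactivity", "phenosimilarity"),
                      max_set_size = 1, min_moa_size = 5, n_draws = 0,
                      fraction = 2 / 3, seed = 1L,
                      summary_stat = c("mean", "median"), ...) {
  task <- match.arg(task)
  summary_stat <- match.arg(summary_stat)
  lines <- sort(unique(profiles$cell_line))
  if (max_set_size > length(lines)) {
    stop("max_set_size exceeds the number of cell lines (", length(lines),
         ")", call. = FALSE)
  }
  sets <- unlist(lapply(seq_len(max_set_size), function(s) {
    utils::combn(lines, s, simplify = FALSE)
  }), recursive = FALSE)
  scores <- score_screen(profiles, annotation, task, min_moa_size, ...)
  res <- dplyr::bind_rows(lapply(sets, function(st) {
    per_moa <- aggregate_set(scores, st)
    tibble::tibble(lines = paste(st, collapse = ";"), task = task,
                   n_lines = length(st), n_moas = nrow(per_moa),
                   summary = summarize_scores(per_moa, summary_stat))
  }))
  if (n_draws > 0) {
    draws <- subsample_summaries(profiles, annotation, task, sets,
                                 n_draws = n_draws, fraction = fraction,
                                 seed = seed, min_moa_size = min_moa_size,
                                 ...)
    res$subsample_mean <- unname(colMeans(draws, na.rm = TRUE))
    res$subsample_sd <- unname(apply(draws, 2, stats::sd, na.rm = TRUE))
    res$subsample_summaries <- lapply(seq_len(ncol(draws)),
                                      function(j) draws[, j])
  }
  ord <- order(-res$summary, res$n_lines, res$lines, method = "radix")
  res[ord, , drop = FALSE]
}
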