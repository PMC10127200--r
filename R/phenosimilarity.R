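#' Within-MOA and nearest-neighbor distance multisets
#'
#' For one MOA's compounds, collects (i) all pairwise Euclidean distances
#' among the MOA's profiles ("within") and (ii), for each MOA compound, its
#' distances to its `k` nearest neighbors among *all* compound profiles in the
#' library — any MOA, self excluded, DMSO excluded ("neighbor"). The neighbor
#' multiset sets the local distance scale each compound lives at; the within
#' multiset is what phenosimilarity compares against it.
#'
#' Ties in neighbor distance are broken by compound identifier (lexicographic)
#' so results are deterministic.
#'
#' @param moa_ids Identifiers of the MOA's compounds (>= 2).
#' @param compound_mat Matrix of all compound profiles, rows named by
#'   compound identifier.
#' @param k Neighbors per compound; default `length(moa_ids) - 1`, making the
#'   within and neighbor multisets size-comparable.
#' @return A `neighbor_distances` list with `within` (choose(n,2) values) and
#'   `neighbor` (n * k values).
#' @export
neighbor_distances <- function(moa_ids, compound_mat, k = NULL) {
  moa_ids <- sort(unique(moa_ids))
  n <- length(moa_ids)
  if (n < 2) stop("MOA needs >= 2 compounds for neighbor distances",
                  call. = FALSE)
  if (is.null(rownames(compound_mat))) {
    stop("compound_mat must have compound identifiers as row names",
         call. = FALSE)
  }
  absent <- setdiff(moa_ids, rownames(compound_mat))
  if (length(absent) > 0) {
    stop("MOA compound(s) missing from library: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (is.null(k)) k <- n - 1
  if (k < 1 || k > nrow(compound_mat) - 1) {
    stop("k must be between 1 and library size - 1 (", nrow(compound_mat) - 1,
         "); got ", k, call. = FALSE)
  }
  mm <- compound_mat[moa_ids, , drop = FALSE]
  within <- as.vector(stats::dist(mm))
  lib_ids <- rownames(compound_mat)
  neighbor <- unlist(lapply(moa_ids, function(id) {
    d <- sqrt(colSums((t(compound_mat) - compound_mat[id, ])^2))
    keep <- lib_ids != id
    d <- d[keep]
    ord <- order(d, lib_ids[keep], method = "radix")
    d[ord][seq_len(k)]
  }), use.names = FALSE)
  structure(list(within = within, neighbor = neighbor),
            class = "neighbor_distances")
}

#' Phenosimilarity score of a neighbor-distance set
#'
#' \eqn{1 - \max(0, \sup_x [F_{neighbor}(x) - F_{within}(x)])}: when an MOA is
#' tightly clustered, each compound's nearest neighbors are its MOA partners,
#' the two distance distributions coincide, and the score is 1. When
#' within-MOA distances are much larger than each compound's local
#' neighborhood scale the neighbor ECDF dominates and the score falls
#' toward 0.
#'
#' @param nd A [neighbor_distances()] object.
#' @return A scalar in \[0, 1\].
#' @export
phenosimilarity_score <- function(nd) {
  1 - max(0, ecdf_sup_diff(nd$neighbor, nd$within))
}

#' Phenosimilarity scores for every (cell line, MOA) pair
#'
#' For each cell line, the neighbor search runs over that line's compound
#' profiles only (DMSO self-profiles are excluded — proximity to DMSO is
#' phenoactivity's job). MOAs need at least two profiled compounds; smaller
#' MOAs are skipped with a warning.
#'
#' @param profiles A `phenotypic_profiles` tibble (see [build_profiles()]).
#' @param annotation A [moa_annotation()] table.
#' @param min_moa_size Minimum compounds per scored MOA (floor of 2).
#' @param k `"auto"` (default, k = n - 1 per MOA) or a fixed positive integer.
#' @return A tibble: `cell_line`, `moa`, `n_compounds`, `score`.
#' @export
score_all_phenosimilarity <- function(profiles, annotation, min_moa_size = 2,
                                      k = "auto") {
  min_moa_size <- max(2, min_moa_size)
  ann <- annotation[annotation$compound %in%
                      profiles$treatment[profiles$role == "compound"], ,
                    drop = FALSE]
  if (nrow(ann) == 0) {
    stop("no overlap between annotated compounds and profiled treatments",
         call. = FALSE)
  }
  out <- lapply(split(profiles, profiles$cell_line), function(pl) {
    pl <- new_profiles(pl, feature_names(profiles))
    comp <- pl[pl$role == "compound", , drop = FALSE]
    cmat <- profile_matrix(new_profiles(comp, feature_names(profiles)))
    per_moa <- split(ann$compound, ann$moa)
    rows <- lapply(names(per_moa), function(m) {
      ids <- intersect(per_moa[[m]], rownames(cmat))
      if (length(ids) < 2) {
        warning("MOA '", m, "' has fewer than 2 profiled compounds in ",
                pl$cell_line[1], "; skipped", call. = FALSE)
        return(NULL)
      }
      if (length(ids) < min_moa_size) return(NULL)
      kk <- if (identical(k, "auto")) NULL else k
      nd <- neighbor_distances(ids, cmat, kk)
      tibble::tibble(cell_line = pl$cell_line[1], moa = m,
                     n_compounds = length(ids),
                     score = phenosimilarity_score(nd))
    })
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    stop("no MOA eligible for phenosimilarity scoring", call. = FALSE)
  }
  dplyr::arrange(res, .data$cell_line, .data$moa)
}
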