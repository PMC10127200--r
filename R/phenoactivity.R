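#' Centroid of the DMSO point cloud
#'
#' @param control_profiles A `phenotypic_profiles` tibble (or numeric matrix)
#'   of DMSO self-profiles; at least two are required.
#' @param centroid `"mean"` (default) or `"median"`, applied coordinate-wise.
#' @return A named numeric vector of length D.
#' @export
dmso_centroid <- function(control_profiles, centroid = c("mean", "median")) {
  centroid <- match.arg(centroid)
  m <- if (is.matrix(control_profiles)) control_profiles
       else profile_matrix(control_profiles, role = "control")
  if (nrow(m) < 2) {
    stop("need at least 2 control profiles to form a DMSO centroid",
         call. = FALSE)
  }
  if (centroid == "mean") colMeans(m) else apply(m, 2, stats::median)
}

row_distances <- function(m, center, metric) {
  if (ncol(m) != length(center)) {
    stop("profile dimension (", ncol(m), ") does not match centroid length (",
         length(center), ")", call. = FALSE)
  }
  if (metric == "euclidean") {
    sqrt(colSums((t(m) - center)^2))
  } else { # cosine distance
    cn <- sqrt(sum(center^2))
    rn <- sqrt(rowSums(m^2))
    1 - as.vector(m %*% center) / (rn * cn)
  }
}

#' Distances of MOA and DMSO profiles to the DMSO centroid
#'
#' Converts the two point clouds into two distance distributions: every MOA
#' compound profile and every DMSO self-profile is reduced to its distance
#' from the DMSO centroid. These distributions carry all the information the
#' phenoactivity score and the outside-the-cloud rule use.
#'
#' The DMSO self-distances define the reference spread of the cloud. A DMSO
#' profile is part of the cloud whose centroid it helps define, so its
#' distance to the pooled centroid is biased low — severely so with few wells
#' in a high-dimensional profile space, which would make *any* independent
#' profile look active. The default `dmso_reference = "loo"` therefore
#' measures each DMSO profile against the centroid of the *other* DMSO
#' profiles, putting the reference distribution on the same footing as the
#' compound distances; `"pooled"` gives the uncorrected distances.
#'
#' @param moa_profiles Profiles (or matrix) of one MOA's compounds, >= 1 row.
#' @param control_profiles DMSO self-profiles (or matrix), >= 2 rows.
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @param centroid Passed to [dmso_centroid()].
#' @param dmso_reference `"loo"` (default) or `"pooled"`; see Details.
#' @return A `distance_set`: list with `reference_centroid`,
#'   `dmso_distances`, `moa_distances`.
#' @export
distance_set <- function(moa_profiles, control_profiles,
                         metric = c("euclidean", "cosine"),
                         centroid = c("mean", "median"),
                         dmso_reference = c("loo", "pooled")) {
  metric <- match.arg(metric)
  centroid <- match.arg(centroid)
  dmso_reference <- match.arg(dmso_reference)
  mm <- if (is.matrix(moa_profiles)) moa_profiles
        else profile_matrix(moa_profiles)
  if (nrow(mm) < 1) stop("MOA has no compound profiles", call. = FALSE)
  cm <- if (is.matrix(control_profiles)) control_profiles
        else profile_matrix(control_profiles, role = "control")
  center <- dmso_centroid(cm, centroid)
  if (dmso_reference == "loo") {
    dd <- vapply(seq_len(nrow(cm)), function(i) {
      rest <- cm[-i, , drop = FALSE]
      ref <- if (centroid == "mean") colMeans(rest)
             else apply(rest, 2, stats::median)
      row_distances(cm[i, , drop = FALSE], ref, metric)
    }, numeric(1))
  } else {
    dd <- row_distances(cm, center, metric)
  }
  structure(
    list(reference_centroid = center,
         dmso_distances = dd,
         moa_distances = row_distances(mm, center, metric)),
    class = "distance_set"
  )
}

#' Phenoactivity score of a distance set
#'
#' One-sided KS statistic measuring how far the MOA's distance distribution
#' sits *above* the DMSO distance distribution:
#' \eqn{\max(0, \sup_x [F_{DMSO}(x) - F_{MOA}(x)])}. It is 0 when MOA
#' distances are stochastically no larger than DMSO's own spread and 1 when
#' every MOA profile lies beyond every DMSO profile.
#'
#' @param ds A [distance_set()].
#' @return A scalar in \[0, 1\].
#' @export
phenoactivity_score <- function(ds) {
  max(0, ecdf_sup_diff(ds$dmso_distances, ds$moa_distances))
}

#' Outside-the-DMSO-cloud rule
#'
#' A compound is called outside the DMSO cloud when its distance to the DMSO
#' centroid is more than one IQR above the median DMSO-to-centroid distance.
#' Quartiles use linear interpolation (`stats::quantile` type 7); the
#' comparison is strict.
#'
#' @param ds A [distance_set()] with >= 2 DMSO distances.
#' @return A list with `threshold` (median + IQR of DMSO distances) and
#'   `n_outside` (number of MOA distances strictly above it).
#' @export
outside_cloud <- function(ds) {
  d <- ds$dmso_distances
  if (length(d) < 2) {
    stop("need >= 2 DMSO distances for the outside-cloud rule", call. = FALSE)
  }
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
  threshold <- stats::median(d) + (q[2] - q[1])
  list(threshold = threshold, n_outside = sum(ds$moa_distances > threshold))
}

#' Phenoactivity scores for every (cell line, MOA) pair
#'
#' For each cell line, forms the DMSO distance distribution from the control
#' self-profiles, then scores each annotated MOA with at least `min_moa_size`
#' profiled compounds. Compounds annotated with several MOAs contribute to
#' each of their MOA point clouds.
#'
#' @param profiles A `phenotypic_profiles` tibble with compound and control
#'   rows (see [build_profiles()]).
#' @param annotation A [moa_annotation()] table.
#' @param min_moa_size Minimum number of profiled compounds per MOA (default 1
#'   for computation; a reporting filter of 5 matches the headline analyses).
#' @param metric,centroid,dmso_reference Passed to [distance_set()].
#' @return A tibble: `cell_line`, `moa`, `n_compounds`, `score`, `n_outside`,
#'   `threshold`.
#' @export
score_all_phenoactivity <- function(profiles, annotation, min_moa_size = 1,
                                    metric = c("euclidean", "cosine"),
                                    centroid = c("mean", "median"),
                                    dmso_reference = c("loo", "pooled")) {
  metric <- match.arg(metric)
  centroid <- match.arg(centroid)
  dmso_reference <- match.arg(dmso_reference)
  ann <- annotation[annotation$compound %in%
                      profiles$treatment[profiles$role == "compound"], ,
                    drop = FALSE]
  if (nrow(ann) == 0) {
    stop("no overlap between annotated compounds and profiled treatments",
         call. = FALSE)
  }
  out <- lapply(split(profiles, profiles$cell_line), function(pl) {
    pl <- new_profiles(pl, feature_names(profiles))
    cm <- profile_matrix(pl, role = "control")
    comp <- pl[pl$role == "compound", , drop = FALSE]
    cmat <- profile_matrix(new_profiles(comp, feature_names(profiles)))
    per_moa <- split(ann$compound, ann$moa)
    rows <- lapply(names(per_moa), function(m) {
      ids <- intersect(per_moa[[m]], rownames(cmat))
      if (length(ids) < min_moa_size || length(ids) < 1) return(NULL)
      ds <- distance_set(cmat[ids, , drop = FALSE], cm, metric, centroid,
                         dmso_reference)
      oc <- outside_cloud(ds)
      tibble::tibble(cell_line = pl$cell_line[1], moa = m,
                     n_compounds = length(ids),
                     score = phenoactivity_score(ds),
                     n_outside = oc$n_outside, threshold = oc$threshold)
    })
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(cell_line = character(), moa = character(),
                          n_compounds = integer(), score = numeric(),
                          n_outside = integer(), threshold = numeric()))
  }
  dplyr::arrange(res, .data$cell_line, .data$moa)
}
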