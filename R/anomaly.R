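# Local Outlier Factor on feature descriptors.
#
# Two local-density variants are provided:
#   * "raw":          lrd(p) = 1 / mean of raw distances d(p, q) over the
#                     k-distance neighborhood N_k(p),
#   * "reachability": the canonical definition, with d(p, q) replaced by
#                     reach-dist_k(p, q) = max(k-distance(q), d(p, q)).
# In both, LOF(p) = mean_{q in N_k(p)} lrd(q) / lrd(p); each lrd(q) is
# computed against the references excluding q itself (leave-one-out), and a
# query exactly equal to one reference drops that single reference.

as_points <- function(x, name = "points") {
  if (is.data.frame(x)) x <- feature_matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_bad_arg(sprintf("`%s` must be finite numeric.", name))
  }
  x
}

#' Pairwise distances between two point sets
#'
#' @param A,B Numeric matrices (one point per row); plain vectors are
#'   treated as 1-D point sets.
#' @param metric `"squared_euclidean"` (the default used throughout the
#'   anomaly stage) or `"euclidean"`.
#' @return `nrow(A)` x `nrow(B)` distance matrix.
#' @export
pairwise_distance <- function(A, B, metric = c("squared_euclidean", "euclidean")) {
  metric <- match.arg(metric)
  A <- as_points(A, "A")
  B <- as_points(B, "B")
  if (ncol(A) != ncol(B)) abort_bad_arg("A and B must have equal dimensionality.")
  # accumulate per dimension rather than expanding the square: exact zeros
  # for coincident points and bit-reproducible ties, which the k-distance
  # neighborhood's tie-inclusion rule relies on
  d2 <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(ncol(A))) {
    d2 <- d2 + outer(A[, j], B[, j], "-")^2
  }
  if (metric == "euclidean") sqrt(d2) else d2
}

query_distances <- function(p, refs, metric) {
  drop(pairwise_distance(matrix(p, nrow = 1), refs, metric))
}

# Index of one reference exactly equal to p, or 0L.
self_match <- function(p, refs) {
  hit <- which(apply(refs, 1L, function(r) all(r == p)))
  if (length(hit) > 0) hit[1] else 0L
}

#' k-distance neighborhood of a query point
#'
#' All references whose distance to `p` does not exceed the k-th smallest
#' distance (ties at the k-distance are included, so the neighborhood may
#' contain more than `k` points). The search is exhaustive.
#'
#' @param p Numeric query vector.
#' @param refs Reference points: matrix (rows), numeric vector (1-D
#'   points), or a feature tibble from [extract_features()].
#' @param k Neighborhood size; must be smaller than the number of
#'   references.
#' @param metric Distance metric, see [pairwise_distance()].
#' @return Integer vector of reference row indices.
#' @export
k_distance_neighborhood <- function(p, refs, k = 5,
                                    metric = c("squared_euclidean", "euclidean")) {
  metric <- match.arg(metric)
  refs <- as_points(refs, "refs")
  check_number(k, "k", min = 1, integerish = TRUE)
  if (k >= nrow(refs)) {
    abort_bad_arg(sprintf("k = %d must be smaller than the number of references (%d).",
                          k, nrow(refs)))
  }
  d <- query_distances(p, refs, metric)
  kdist <- sort(d, partial = k)[k]
  which(d <= kdist)
}

# k-distance of reference i within refs excluding i itself.
ref_k_distance <- function(D, i, k) {
  sort(D[i, -i], partial = k)[k]
}

lrd_from_distances <- function(d_pq, kdist_q = NULL) {
  reach <- if (is.null(kdist_q)) d_pq else pmax(kdist_q, d_pq)
  m <- mean(reach)
  if (m == 0) Inf else 1 / m
}

#' Local reachability density of a point
#'
#' Inverse of the mean (reachability) distance from `p` to its k-distance
#' neighborhood among the references. With `variant = "raw"` the raw
#' distance is used; with `variant = "reachability"` the canonical
#' reach-dist (each neighbor's own k-distance, computed leave-one-out among
#' the references, floors the distance). A query exactly equal to one
#' reference drops that reference first. If every neighbor lies at
#' distance 0 the density is infinite and `Inf` is returned.
#'
#' @inheritParams k_distance_neighborhood
#' @param variant `"raw"` or `"reachability"`.
#' @return Positive real (possibly `Inf`).
#' @export
lrd <- function(p, refs, k = 5, metric = c("squared_euclidean", "euclidean"),
                variant = c("raw", "reachability")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  refs <- as_points(refs, "refs")
  sm <- self_match(p, refs)
  keep <- seq_len(nrow(refs))
  if (sm > 0) keep <- keep[-sm]
  refs_p <- refs[keep, , drop = FALSE]
  nb <- k_distance_neighborhood(p, refs_p, k, metric)
  d <- query_distances(p, refs_p, metric)[nb]
  kd <- NULL
  if (variant == "reachability") {
    # each neighbor's k-distance is taken within the full reference set
    # minus that neighbor only (the query's duplicate, if any, stays in)
    D <- pairwise_distance(refs, refs, metric)
    kd <- vapply(keep[nb], function(i) ref_k_distance(D, i, k), numeric(1))
  }
  lrd_from_distances(d, kd)
}

#' Local Outlier Factor of a query point
#'
#' `LOF(p)` is the mean ratio of the local (reachability) densities of the
#' points in `p`'s k-distance neighborhood to `p`'s own density; values
#' near 1 indicate `p` sits in a region of density comparable to its
#' neighbors, values well above 1 indicate an outlier. Each neighbor's
#' density is computed against the references excluding that neighbor, and
#' a query exactly equal to one reference is scored leave-one-out. A query
#' duplicating a point of an infinitely dense spot (its own lrd infinite)
#' is not an outlier: its LOF is defined as 1.
#'
#' @inheritParams lrd
#' @return Scalar LOF value (positive; possibly `Inf` when a neighbor's
#'   density is infinite but the query's is not).
#' @export
lof_score <- function(p, refs, k = 5, metric = c("squared_euclidean", "euclidean"),
                      variant = c("raw", "reachability")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  refs <- as_points(refs, "refs")
  sm <- self_match(p, refs)
  keep <- seq_len(nrow(refs))
  if (sm > 0) keep <- keep[-sm]
  if (length(keep) <= k) {
    abort_bad_arg("too few references for the requested k.")
  }
  # lrd() handles the leave-one-out exclusion internally, so both the
  # query's density and each neighbor's density are taken against the full
  # reference set minus the point whose density is being measured.
  lrd_p <- lrd(p, refs, k, metric, variant)
  if (!is.finite(lrd_p)) return(1)
  nb <- k_distance_neighborhood(p, refs[keep, , drop = FALSE], k, metric)
  lrd_q <- vapply(keep[nb], function(i) {
    lrd(refs[i, ], refs, k, metric, variant)
  }, numeric(1))
  mean(lrd_q / lrd_p)
}

#' Fit a Local Outlier Factor reference model
#'
#' Stores the reference descriptors and precomputes, per reference, its
#' leave-one-out k-distance and local (reachability) density, so queries
#' can be scored against the fitted set.
#'
#' @param refs Reference descriptors: a feature tibble from
#'   [extract_features()] (with a `label` column), a numeric matrix, or a
#'   numeric vector of 1-D points.
#' @param k Neighborhood size (default 5).
#' @param metric Distance metric (default `"squared_euclidean"`).
#' @param variant Density variant (default `"reachability"`, the canonical
#'   definition; `"raw"` uses raw mean distances).
#' @param fit_scope For feature tibbles: `"normal_only"` keeps only class-0
#'   descriptors as references (novelty-detection reading), `"all_cohort"`
#'   keeps classes 0 and 1.
#' @param include_textures For feature tibbles: keep class-2 (texture)
#'   descriptors in the reference set (default `FALSE`).
#' @return A `lof_model` object.
#' @export
lof_fit <- function(refs, k = 5, metric = c("squared_euclidean", "euclidean"),
                    variant = c("reachability", "raw"),
                    fit_scope = c("normal_only", "all_cohort"),
                    include_textures = FALSE) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  fit_scope <- match.arg(fit_scope)
  ids <- NULL
  if (is.data.frame(refs) && "label" %in% names(refs)) {
    keep <- if (fit_scope == "normal_only") refs$label == 0L else refs$label %in% c(0L, 1L)
    if (include_textures) keep <- keep | refs$label == 2L
    refs <- refs[keep, , drop = FALSE]
    ids <- refs$case_id
  }
  X <- as_points(refs, "refs")
  check_number(k, "k", min = 1, integerish = TRUE)
  if (nrow(X) <= k) {
    abort_bad_arg(sprintf("need more than k = %d references, got %d.", k, nrow(X)))
  }
  D <- pairwise_distance(X, X, metric)
  kdist <- vapply(seq_len(nrow(X)), function(i) ref_k_distance(D, i, k), numeric(1))
  lrd_refs <- vapply(seq_len(nrow(X)), function(i) {
    d_i <- D[i, -i]
    nb <- which(d_i <= kdist[i])        # indices into refs excluding i
    full <- seq_len(nrow(X))[-i][nb]    # back to full indexing
    kd <- if (variant == "reachability") kdist[full] else NULL
    lrd_from_distances(d_i[nb], kd)
  }, numeric(1))
  structure(
    list(refs = X, ids = ids, k = as.integer(k), metric = metric,
         variant = variant, fit_scope = fit_scope,
         kdist = kdist, lrd_refs = lrd_refs),
    class = "lof_model"
  )
}

#' @export
print.lof_model <- function(x, ...) {
  cat(sprintf("<lof_model> %d references (dim %d), k = %d, %s metric, %s variant\n",
              nrow(x$refs), ncol(x$refs), x$k, x$metric, x$variant))
  invisible(x)
}

#' Score queries against a fitted LOF model
#'
#' @param object A `lof_model` from [lof_fit()].
#' @param queries Query descriptors: feature tibble, matrix, or vector of
#'   1-D points. A query exactly equal to a stored reference is scored
#'   leave-one-out.
#' @param ... Unused.
#' @return Tibble with columns `case_id`, `label` (`NA` when unknown) and
#'   `lof`.
#' @export
predict.lof_model <- function(object, queries, ...) {
  ids <- NULL; labels <- NULL
  if (is.data.frame(queries)) {
    ids <- queries$case_id
    labels <- queries$label
  }
  Q <- as_points(queries, "queries")
  if (ncol(Q) != ncol(object$refs)) {
    abort_bad_arg("queries and references must have equal dimensionality.")
  }
  lof <- vapply(seq_len(nrow(Q)), function(i) {
    score_one(object, Q[i, ])
  }, numeric(1))
  tibble::tibble(
    case_id = ids %||% sprintf("q%03d", seq_len(nrow(Q))),
    label = labels %||% NA_integer_,
    lof = lof
  )
}

score_one <- function(model, p) {
  X <- model$refs
  d <- query_distances(p, X, model$metric)
  sm <- self_match(p, X)
  keep <- seq_len(nrow(X))
  if (sm > 0) keep <- keep[-sm]
  d <- d[keep]
  kdist_p <- sort(d, partial = model$k)[model$k]
  nb <- which(d <= kdist_p)
  full <- keep[nb]
  kd <- if (model$variant == "reachability") model$kdist[full] else NULL
  lrd_p <- lrd_from_distances(d[nb], kd)
  if (!is.finite(lrd_p)) return(1)
  mean(model$lrd_refs[full] / lrd_p)
}

#' Threshold LOF scores into normal/abnormal decisions
#'
#' @param scores Tibble with a `lof` (or `score`) column, or a numeric
#'   vector.
#' @param threshold Decision threshold; a case is abnormal iff its score is
#'   strictly greater than `threshold` (typically the Youden-index
#'   threshold from [youden_threshold()]).
#' @return For tibbles, the tibble with an added `decision` column
#'   (`"normal"` / `"abnormal"`); for vectors, a character vector.
#' @export
classify_scores <- function(scores, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    abort_bad_arg("`threshold` must be a single number (infinities allowed).")
  }
  decide <- function(v) ifelse(v > threshold, "abnormal", "normal")
  if (is.data.frame(scores)) {
    col <- if ("lof" %in% names(scores)) "lof" else "score"
    return(dplyr::mutate(scores, decision = decide(.data[[col]])))
  }
  decide(scores)
}
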