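# ROC / precision-recall evaluation with Youden operating point, DeLong
# confidence interval for the ROC-AUC and stratified case-resampling
# bootstrap intervals for the remaining metrics.

check_scored_set <- function(scores, labels, need_neg = TRUE) {
  if (length(scores) != length(labels)) {
    abort_bad_arg("`scores` and `labels` must have equal length.")
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    abort_bad_arg("`scores` must be finite.")
  }
  if (!all(labels %in% c(0, 1))) {
    abort_bad_arg("`labels` must be binary (1 = abnormal/positive).")
  }
  if (sum(labels == 1) == 0) {
    rlang::abort("at least one positive case is required.",
                 class = "deeplof_undefined_metric")
  }
  if (need_neg && sum(labels == 0) == 0) {
    rlang::abort("at least one negative case is required.",
                 class = "deeplof_undefined_metric")
  }
  invisible(TRUE)
}

#' ROC area under the curve
#'
#' The Mann-Whitney pair-counting statistic: the proportion of
#' positive/negative pairs in which the positive scores higher, ties
#' counted half.
#'
#' @param scores Numeric scores (larger = more abnormal).
#' @param labels Binary labels, 1 = abnormal/positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  check_scored_set(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall area under the curve (average precision)
#'
#' Step-wise average precision: sum over distinct score thresholds of the
#' recall increment times the precision at that threshold. No linear
#' interpolation between PR points is used.
#'
#' @inheritParams roc_auc
#' @return Average precision in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  check_scored_set(scores, labels, need_neg = FALSE)
  n1 <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l == 1)
  fp <- cumsum(l == 0)
  last_of_threshold <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_threshold]
  fp <- fp[last_of_threshold]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Youden-index operating point
#'
#' Maximises `J = sensitivity + specificity - 1` over all candidate
#' thresholds (midpoints between adjacent distinct scores, plus infinite
#' sentinels), with the decision rule `score > threshold`. When several
#' thresholds attain the maximum J, the one with the highest sensitivity is
#' returned.
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_threshold <- function(scores, labels) {
  check_scored_set(scores, labels)
  s <- sort(unique(scores))
  candidates <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(candidates, function(t) mean(pos > t), numeric(1))
  spec <- vapply(candidates, function(t) mean(neg <= t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(sens[best])]
  list(threshold = candidates[best], sensitivity = sens[best],
       specificity = spec[best], j = j[best])
}

#' Stratified bootstrap percentile confidence interval
#'
#' Case-resampling bootstrap stratified by class: positives are resampled
#' among positives and negatives among negatives (so no resample loses a
#' class), and the 2.5/97.5 percentiles of the replicated metric form the
#' 95% interval. Resamples on which the metric is undefined are redrawn.
#'
#' @inheritParams roc_auc
#' @param metric_fn Function of `(scores, labels)` returning a scalar.
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param seed Integer seed.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(scores, labels, metric_fn, n_boot = 2000, seed = 1L) {
  check_number(n_boot, "n_boot", min = 100, integerish = TRUE)
  point <- metric_fn(scores, labels)   # errors here propagate: metric must be defined
  if (!is.finite(point)) {
    abort_bad_arg("metric is not finite on the original set.")
  }
  pos_idx <- which(labels == 1)
  neg_idx <- which(labels == 0)
  reps <- withr::with_seed(derive_seed(seed, 6L), {
    vapply(seq_len(n_boot), function(b) {
      for (try in 1:100) {
        idx <- c(sample(pos_idx, length(pos_idx), replace = TRUE),
                 sample(neg_idx, length(neg_idx), replace = TRUE))
        v <- tryCatch(metric_fn(scores[idx], labels[idx]), error = function(e) NA_real_)
        if (is.finite(v)) return(v)
      }
      NA_real_
    }, numeric(1))
  })
  ci <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  c(lower = ci[1], upper = ci[2])
}

#' DeLong confidence interval for the ROC-AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC from the DeLong
#' structural components (placement values): `V10_i` is the mean kernel
#' over negatives for positive `i`, `V01_j` the mean kernel over positives
#' for negative `j`, and `var = S10/n1 + S01/n0` with the sample variances
#' of the components. The 95% interval is the normal approximation,
#' clipped to \[0, 1\].
#'
#' @inheritParams roc_auc
#' @return List with `auc`, `var`, `ci` (length-2 vector).
#' @export
delong_ci <- function(scores, labels) {
  check_scored_set(scores, labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  if (n1 < 2 || n0 < 2) {
    abort_bad_arg("DeLong variance needs at least two cases per class.")
  }
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  auc <- mean(psi)
  v <- stats::var(v10) / n1 + stats::var(v01) / n0
  half <- stats::qnorm(0.975) * sqrt(v)
  list(auc = auc, var = v,
       ci = c(max(0, auc - half), min(1, auc + half)))
}

#' Assemble a full evaluation report
#'
#' Computes ROC-AUC (with DeLong 95% CI), PR-AUC, and the Youden-index
#' sensitivity/specificity operating point, with stratified bootstrap 95%
#' intervals for sensitivity, specificity and PR-AUC.
#'
#' @param data A data frame with columns `score` and `label` (1 =
#'   abnormal), e.g. the scores tibble of a pipeline arm; alternatively
#'   pass `scores`/`labels` vectors.
#' @param scores,labels Used when `data` is `NULL`.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @param threshold_source Provenance tag for the operating threshold
#'   (`"test_youden"` when the Youden index is taken on the test scores, as
#'   in the reference protocol).
#' @return An `eval_report` object.
#' @export
build_report <- function(data = NULL, scores = NULL, labels = NULL,
                         n_boot = 2000, seed = 1L,
                         threshold_source = "test_youden") {
  if (!is.null(data)) {
    col <- if ("score" %in% names(data)) "score" else "lof"
    scores <- data[[col]]
    labels <- data$label
  }
  check_scored_set(scores, labels)
  yj <- youden_threshold(scores, labels)
  dl <- delong_ci(scores, labels)
  sens_fn <- function(s, l) {
    y <- youden_threshold(s, l); y$sensitivity
  }
  spec_fn <- function(s, l) {
    y <- youden_threshold(s, l); y$specificity
  }
  report <- structure(
    list(
      roc_auc = dl$auc,
      pr_auc = pr_auc(scores, labels),
      sensitivity = yj$sensitivity,
      specificity = yj$specificity,
      threshold = yj$threshold,
      threshold_source = threshold_source,
      ci_roc_auc = unname(dl$ci),
      ci_pr_auc = unname(bootstrap_ci(scores, labels, pr_auc, n_boot, derive_seed(seed, 11L))),
      ci_sens = unname(bootstrap_ci(scores, labels, sens_fn, n_boot, derive_seed(seed, 12L))),
      ci_spec = unname(bootstrap_ci(scores, labels, spec_fn, n_boot, derive_seed(seed, 13L))),
      n_bootstrap = as.integer(n_boot),
      seed = as.integer(seed),
      n_pos = sum(labels == 1),
      n_neg = sum(labels == 0)
    ),
    class = "eval_report"
  )
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("<eval_report> n = %d (%d abnormal)\n",
           "  ROC-AUC %.3f (DeLong 95%% CI %.3f-%.3f)\n",
           "  PR-AUC  %.3f (boot   95%% CI %.3f-%.3f)\n",
           "  sens %.3f / spec %.3f at threshold %.4g (%s)\n"),
    x$n_pos + x$n_neg, x$n_pos,
    x$roc_auc, x$ci_roc_auc[1], x$ci_roc_auc[2],
    x$pr_auc, x$ci_pr_auc[1], x$ci_pr_auc[2],
    x$sensitivity, x$specificity, x$threshold, x$threshold_source))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per metric: `metric`, `estimate`,
#'   `conf.low`, `conf.high`, `ci_method`.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    metric = c("roc_auc", "pr_auc", "sensitivity", "specificity"),
    estimate = c(x$roc_auc, x$pr_auc, x$sensitivity, x$specificity),
    conf.low = c(x$ci_roc_auc[1], x$ci_pr_auc[1], x$ci_sens[1], x$ci_spec[1]),
    conf.high = c(x$ci_roc_auc[2], x$ci_pr_auc[2], x$ci_sens[2], x$ci_spec[2]),
    ci_method = c("delong", "bootstrap", "bootstrap", "bootstrap")
  )
}

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble of the four headline metrics, threshold and
#'   class sizes.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    roc_auc = x$roc_auc, pr_auc = x$pr_auc,
    sensitivity = x$sensitivity, specificity = x$specificity,
    threshold = x$threshold, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Serialize / deserialize an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @return `report_to_json()` returns a JSON string;
#'   `report_from_json()` its inverse.
#' @export
report_to_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
}

#' @rdname report_to_json
#' @param json JSON string from [report_to_json()].
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$n_bootstrap <- as.integer(x$n_bootstrap)
  x$seed <- as.integer(x$seed)
  x$n_pos <- as.integer(x$n_pos)
  x$n_neg <- as.integer(x$n_neg)
  structure(x, class = "eval_report")
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, ordered for
#'   plotting.
#' @export
roc_points <- function(scores, labels) {
  check_scored_set(scores, labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tibble::tibble(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(neg > t), numeric(1)),
    tpr = vapply(thr, function(t) mean(pos > t), numeric(1))
  )
}

#' Precision-recall curve points
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(scores, labels) {
  check_scored_set(scores, labels, need_neg = FALSE)
  n1 <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l == 1)
  fp <- cumsum(l == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tibble::tibble(
    threshold = s[last],
    recall = tp[last] / n1,
    precision = tp[last] / (tp[last] + fp[last])
  )
}
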