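#' Configure an ablation experiment
#'
#' Bundles everything needed to run the ablation ladder over a synthetic
#' cohort: the cohort specification, split settings, augmentation and
#' training configurations, the L2-head scale, LOF settings, evaluation
#' settings, the set of arms and the seeds.
#'
#' The four arms mirror the reference ablation ladder:
#' \describe{
#'   \item{`conventional`}{2-class softmax network, no textures, no L2
#'     constraint; score = class-1 probability.}
#'   \item{`texture`}{3-class softmax with the texture class; binary score
#'     renormalised over the cohort classes.}
#'   \item{`texture_l2`}{as `texture`, with the L2-constrained head.}
#'   \item{`texture_l2_lof`}{features of the L2 network scored by LOF
#'     fitted on the normal-class training descriptors.}
#' }
#'
#' @param spec A [cohort_spec()]; its seed is re-derived per experiment
#'   seed.
#' @param fractions Train/val/test fractions.
#' @param explicit_counts Optional per-class per-split counts (see
#'   [stratified_split()]).
#' @param augment An [augment_config()].
#' @param training A [training_config()].
#' @param alpha L2-constraint scale used by the L2 arms.
#' @param lof List of LOF settings: `k`, `metric`, `variant`, `fit_scope`,
#'   `include_textures`.
#' @param n_boot Bootstrap replicates for the per-arm reports.
#' @param arms Character subset of the four arm names.
#' @param seeds Integer vector of experiment seeds.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(spec = cohort_spec(),
                              fractions = c(0.6, 0.2, 0.2),
                              explicit_counts = NULL,
                              augment = augment_config(),
                              training = training_config(),
                              alpha = 80,
                              lof = list(k = 5, metric = "squared_euclidean",
                                         variant = "reachability",
                                         fit_scope = "normal_only",
                                         include_textures = FALSE),
                              n_boot = 500,
                              arms = c("conventional", "texture",
                                       "texture_l2", "texture_l2_lof"),
                              seeds = 1:5) {
  arms <- match.arg(arms, several.ok = TRUE)
  if (length(arms) == 0L) abort_bad_arg("at least one arm is required.")
  structure(
    list(spec = spec, fractions = fractions, explicit_counts = explicit_counts,
         augment = augment, training = training, alpha = alpha, lof = lof,
         n_boot = n_boot, arms = arms, seeds = as.integer(seeds)),
    class = "experiment_config"
  )
}

#' Scaled-down synthetic benchmark configuration
#'
#' The default desk-scale benchmark: the full 190/55 imbalanced cohort
#' mirrored at 32x32 pixels with the `tiny_cnn` backbone trained from
#' scratch (Adam 1e-3, at most 25 epochs, patience 8). This keeps the
#' class structure and imbalance of the emulated study while remaining
#' runnable in minutes on one CPU.
#'
#' @param seeds Experiment seeds (default 1:5).
#' @param arms Arms to run (default `conventional` and `texture_l2_lof`,
#'   the two ends of the ladder).
#' @return An `experiment_config`.
#' @export
default_benchmark_config <- function(seeds = 1:5,
                                     arms = c("conventional", "texture_l2_lof")) {
  experiment_config(
    spec = cohort_spec(image_size = 32),
    training = training_config(backbone = "tiny_cnn", learning_rate = 1e-3,
                               max_epochs = 25L, early_stop_patience = 8L,
                               input_size = 32L, feature_width = 32L),
    n_boot = 200,
    arms = arms,
    seeds = seeds
  )
}

split_cases <- function(cohort, split) {
  ids <- cohort_manifest(cohort)$case_id
  pick <- function(want) cohort[ids %in% want]
  list(train = pick(split$train), val = pick(split$val), test = pick(split$test))
}

#' Run one ablation arm
#'
#' Trains the arm's network on the train split (model selection on the
#' validation loss), scores the test split only, and evaluates. The
#' `conventional` arm never touches the texture images. The operating
#' threshold is the Youden-index threshold on the test scores, flagged as
#' `threshold_source = "test_youden"` in the report.
#'
#' @param arm One of `"conventional"`, `"texture"`, `"texture_l2"`,
#'   `"texture_l2_lof"`.
#' @param splits List with elements `train`, `val`, `test`, each a list of
#'   `grayscale_pair_case`.
#' @param textures List of `texture_image` (ignored by the conventional
#'   arm).
#' @param config An [experiment_config()].
#' @param seed Integer seed for this run.
#' @return An `arm_result`: list with `arm`, `seed`, `report`
#'   (an `eval_report`), `scores` (tibble case_id/label/score), `history`,
#'   `best_epoch`.
#' @export
run_arm <- function(arm, splits, textures, config, seed = 1L) {
  arm <- match.arg(arm, c("conventional", "texture", "texture_l2", "texture_l2_lof"))
  for (s in c("train", "val", "test")) {
    if (length(splits[[s]] %||% list()) == 0L) {
      rlang::abort(sprintf("missing or empty '%s' split.", s),
                   class = "deeplof_configuration_error")
    }
  }
  use_textures <- arm != "conventional"
  use_l2 <- arm %in% c("texture_l2", "texture_l2_lof")
  n_classes <- if (arm == "conventional") 2L else 3L

  tc <- config$training
  tc$seed <- derive_seed(seed, 21L)
  head <- l2_head_config(alpha = if (use_l2) config$alpha else NULL,
                         n_classes = n_classes)
  model <- build_model(tc, head)
  model <- train_model(model, splits$train, splits$val,
                       textures = if (use_textures) textures else NULL,
                       augment = config$augment, config = tc)

  if (arm == "texture_l2_lof") {
    train_feats <- extract_features(model, splits$train)
    lof <- lof_fit(train_feats, k = config$lof$k, metric = config$lof$metric,
                   variant = config$lof$variant, fit_scope = config$lof$fit_scope,
                   include_textures = isTRUE(config$lof$include_textures))
    test_feats <- extract_features(model, splits$test)
    scored <- predict(lof, test_feats)
    scores <- dplyr::transmute(scored, case_id = .data$case_id,
                               label = .data$label, score = .data$lof)
  } else {
    probs <- predict_softmax(model, splits$test)
    scores <- dplyr::select(binary_anomaly_score(probs),
                            "case_id", "label", "score")
  }
  report <- build_report(scores, n_boot = config$n_boot,
                         seed = derive_seed(seed, 22L),
                         threshold_source = "test_youden")
  structure(
    list(arm = arm, seed = as.integer(seed), report = report, scores = scores,
         history = model$history, best_epoch = model$best_epoch),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s (seed %d): ROC-AUC %.3f, PR-AUC %.3f, best epoch %d\n",
              x$arm, x$seed, x$report$roc_auc, x$report$pr_auc, x$best_epoch))
  invisible(x)
}

#' Run the full ablation experiment
#'
#' For every seed: generates the synthetic cohort and texture library,
#' performs the stratified split, runs every requested arm, and aggregates
#' the per-arm metrics across seeds by the median. Test cases are never
#' visible to training, augmentation, LOF fitting, or model selection.
#'
#' @param config An [experiment_config()], e.g.
#'   [default_benchmark_config()].
#' @param out Optional directory; when given, the per-arm reports, scores
#'   and summary tables are written there as JSON/CSV.
#' @param quiet Suppress progress messages.
#' @return An `ablation_report`: list with `results` (list of
#'   `arm_result`), `summary` (per-arm per-seed metric tibble), `medians`
#'   (per-arm median metrics), `config`.
#' @export
run_experiment <- function(config = default_benchmark_config(), out = NULL,
                           quiet = FALSE) {
  results <- list()
  for (seed in config$seeds) {
    spec <- config$spec
    spec$seed <- derive_seed(seed, 31L)
    cohort <- generate_cohort(spec)
    textures <- generate_texture_library(spec$n_textures,
                                         size = max(spec$image_size, 2L * config$training$input_size %/% 2L),
                                         seed = derive_seed(seed, 32L))
    split <- stratified_split(cohort, fractions = config$fractions,
                              seed = derive_seed(seed, 33L),
                              explicit_counts = config$explicit_counts)
    splits <- split_cases(cohort, split)
    for (arm in config$arms) {
      if (!quiet) message(sprintf("[seed %d] running arm '%s' ...", seed, arm))
      res <- run_arm(arm, splits, textures, config, seed = seed)
      results[[length(results) + 1L]] <- res
      if (!is.null(out)) persist_arm_result(res, out)
    }
  }
  summary <- purrr::map_dfr(results, function(r) {
    dplyr::bind_cols(tibble::tibble(arm = r$arm, seed = r$seed),
                     glance(r$report))
  })
  medians <- summary |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(dplyr::across(c("roc_auc", "pr_auc", "sensitivity", "specificity"),
                                   stats::median),
                     n_seeds = dplyr::n(), .groups = "drop")
  rep <- structure(
    list(results = results, summary = summary, medians = medians, config = config),
    class = "ablation_report"
  )
  if (!is.null(out)) {
    utils::write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)
    utils::write.csv(medians, file.path(out, "medians.csv"), row.names = FALSE)
  }
  rep
}

persist_arm_result <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_seed%d", res$arm, res$seed)
  writeLines(report_to_json(res$report), file.path(out, paste0(stem, "_report.json")))
  utils::write.csv(res$scores, file.path(out, paste0(stem, "_scores.csv")),
                   row.names = FALSE)
  utils::write.csv(res$history, file.path(out, paste0(stem, "_history.csv")),
                   row.names = FALSE)
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("<ablation_report> %d arm runs over %d seeds\n",
              length(x$results), length(x$config$seeds)))
  print(x$medians)
  invisible(x)
}

#' Per-arm per-seed metrics of an ablation experiment
#'
#' @param x An `ablation_report`.
#' @param ... Unused.
#' @return Tibble with columns `arm`, `seed` and the report metrics.
#' @export
tidy.ablation_report <- function(x, ...) x$summary

#' Per-arm median metrics of an ablation experiment
#'
#' @param x An `ablation_report`.
#' @param ... Unused.
#' @return Tibble of per-arm medians across seeds.
#' @export
glance.ablation_report <- function(x, ...) x$medians

#' Read and write experiment configurations as YAML
#'
#' Serializes an [experiment_config()] (cohort spec, augmentation, training,
#' head, LOF and evaluation settings, arms, seeds) to a YAML file with the
#' method defaults spelled out (`alpha: 80`, `k: 5`, `input_size: 100`,
#' `learning_rate: 1e-5`, `batch_size: 1`, `max_epochs: 500`,
#' `frozen_layers: 10`), and reads such a file back into a config object.
#'
#' @param config An `experiment_config`.
#' @param path File path of the YAML document.
#' @return `write_experiment_yaml()` returns `path` invisibly;
#'   `read_experiment_yaml()` returns an `experiment_config`.
#' @export
write_experiment_yaml <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort_bad_arg("the 'yaml' package is required for YAML serialization.")
  }
  doc <- list(
    cohort = unclass(config$spec),
    split = list(fractions = config$fractions),
    augmentation = unclass(config$augment),
    training = unclass(config$training),
    head = list(alpha = config$alpha),
    lof = config$lof,
    evaluation = list(n_boot = config$n_boot),
    arms = as.list(config$arms),
    seeds = as.list(config$seeds)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_experiment_yaml
#' @export
read_experiment_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort_bad_arg("the 'yaml' package is required for YAML serialization.")
  }
  doc <- yaml::read_yaml(path)
  call_with_known <- function(fn, args) {
    args <- lapply(args, function(a) if (length(a) > 1) unlist(a) else a)
    do.call(fn, args[intersect(names(args), names(formals(fn)))])
  }
  experiment_config(
    spec = call_with_known(cohort_spec, doc$cohort),
    fractions = unlist(doc$split$fractions),
    augment = call_with_known(augment_config, doc$augmentation),
    training = call_with_known(training_config, doc$training),
    alpha = doc$head$alpha,
    lof = doc$lof,
    n_boot = doc$evaluation$n_boot,
    arms = unlist(doc$arms),
    seeds = unlist(doc$seeds)
  )
}
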