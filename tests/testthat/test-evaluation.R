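test_that("roc_auc matches hand-counted and degenerate cases", {
  expect_identical(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_identical(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 1)), 5 / 6)
  expect_error(roc_auc(c(1, 2), c(1, 1)), class = "deeplof_undefined_metric")
})

test_that("roc_auc equals pair counting, survives monotone maps, complements", {
  for (seed in 1:8) {
    set <- random_scored_set(7, 12, ties = seed %% 2 == 0, seed = seed)
    auc <- roc_auc(set$scores, set$labels)
    expect_equal(auc, oracle_auc(set$scores, set$labels), tolerance = 1e-12)
    # invariance under a strictly increasing transform
    expect_equal(roc_auc(exp(set$scores / 2), set$labels), auc, tolerance = 1e-12)
    if (seed %% 2 == 1) {   # no ties
      expect_equal(roc_auc(-set$scores, set$labels), 1 - auc, tolerance = 1e-12)
    }
    # trapezoidal integration of the ROC curve agrees
    pts <- roc_points(set$scores, set$labels)
    trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
    expect_equal(trap, auc, tolerance = 1e-12)
  }
})

test_that("average precision matches worked examples", {
  expect_identical(pr_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(pr_auc(c(4, 3, 2, 1), c(1, 0, 1, 0)), 5 / 6)
  # all scores tied: single PR point at full recall, precision = prevalence
  expect_equal(pr_auc(rep(1, 10), rep(c(1, 0), c(3, 7))), 0.3)
})

test_that("the Youden point maximises J with the documented tie-break", {
  y <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_identical(y$sensitivity, 1)
  expect_identical(y$specificity, 1)
  expect_true(y$threshold > 0.2 && y$threshold < 0.8)

  # equal scores: no discrimination
  expect_identical(youden_threshold(rep(2, 6), rep(c(1, 0), 3))$j, 0)

  for (seed in 1:10) {
    set <- random_scored_set(6, 9, ties = seed %% 2 == 0, seed = 100 + seed)
    y <- youden_threshold(set$scores, set$labels)
    expect_equal(y$j, oracle_max_j(set$scores, set$labels), tolerance = 1e-12)
    # reported operating point is consistent with the threshold
    expect_equal(y$sensitivity,
                 mean(set$scores[set$labels == 1] > y$threshold))
    expect_equal(y$specificity,
                 mean(set$scores[set$labels == 0] <= y$threshold))
  }
})

test_that("bootstrap intervals are deterministic and cover the point estimate", {
  set <- random_scored_set(15, 25, seed = 3)
  ci1 <- bootstrap_ci(set$scores, set$labels, roc_auc, n_boot = 300, seed = 4)
  ci2 <- bootstrap_ci(set$scores, set$labels, roc_auc, n_boot = 300, seed = 4)
  expect_identical(ci1, ci2)
  auc <- roc_auc(set$scores, set$labels)
  expect_lte(ci1[["lower"]], auc)
  expect_gte(ci1[["upper"]], auc)
  # constant metric: zero-width interval at the constant
  const <- bootstrap_ci(set$scores, set$labels, function(s, l) 0.77,
                        n_boot = 100, seed = 1)
  expect_identical(unname(const), c(0.77, 0.77))
})

test_that("DeLong point estimate is the AUC and its variance matches the oracle", {
  for (seed in 1:6) {
    set <- random_scored_set(10, 10, ties = seed %% 2 == 0, seed = 200 + seed)
    dl <- delong_ci(set$scores, set$labels)
    expect_identical(dl$auc, roc_auc(set$scores, set$labels))
    expect_equal(dl$var, oracle_delong_var(set$scores, set$labels),
                 tolerance = 1e-12)
    expect_true(dl$ci[1] >= 0 && dl$ci[2] <= 1)
    expect_true(dl$ci[1] <= dl$auc && dl$auc <= dl$ci[2])
  }
})

test_that("DeLong interval narrows with sample size", {
  big <- random_scored_set(200, 200, seed = 7)
  small <- random_scored_set(20, 20, seed = 7)
  expect_lt(diff(delong_ci(big$scores, big$labels)$ci),
            diff(delong_ci(small$scores, small$labels)$ci))
})

test_that("DeLong agrees with the pROC reference implementation", {
  set <- random_scored_set(18, 30, seed = 9)
  dl <- delong_ci(set$scores, set$labels)
  proc_ci <- as.numeric(pROC::ci.auc(pROC::roc(set$labels, set$scores,
                                               direction = "<", quiet = TRUE),
                                     method = "delong"))
  expect_equal(dl$auc, proc_ci[2], tolerance = 1e-12)
  expect_equal(dl$ci, proc_ci[c(1, 3)], tolerance = 1e-9)
})

test_that("reports assemble all Table-style metrics and round-trip as JSON", {
  perfect <- build_report(scores = c(0.1, 0.2, 0.8, 0.9),
                          labels = c(0, 0, 1, 1), n_boot = 100, seed = 1)
  expect_identical(perfect$roc_auc, 1)
  expect_identical(perfect$pr_auc, 1)
  expect_identical(perfect$sensitivity, 1)
  expect_identical(perfect$specificity, 1)

  set <- random_scored_set(12, 30, seed = 10)
  rep <- build_report(scores = set$scores, labels = set$labels,
                      n_boot = 150, seed = 2)
  td <- tidy(rep)
  expect_identical(td$metric, c("roc_auc", "pr_auc", "sensitivity", "specificity"))
  expect_true(all(td$estimate >= 0 & td$estimate <= 1))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_identical(rep$threshold_source, "test_youden")

  back <- report_from_json(report_to_json(rep))
  expect_equal(unclass(back)[names(unclass(rep))], unclass(rep), tolerance = 1e-12)
  expect_identical(nrow(glance(rep)), 1L)
})

test_that("curve point tables are valid plotting inputs", {
  set <- random_scored_set(8, 12, seed = 11)
  rp <- roc_points(set$scores, set$labels)
  expect_identical(rp$fpr[1], 0)
  expect_identical(rp$tpr[nrow(rp)], 1)
  expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))
  pp <- pr_points(set$scores, set$labels)
  expect_true(all(pp$precision >= 0 & pp$precision <= 1))
  expect_identical(pp$recall[nrow(pp)], 1)
  expect_s3_class(plot_roc(set$scores, set$labels), "ggplot")
  expect_s3_class(plot_pr(set$scores, set$labels), "ggplot")
})
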