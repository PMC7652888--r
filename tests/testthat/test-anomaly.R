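test_that("pairwise distances match hand arithmetic and a double-loop oracle", {
  expect_identical(pairwise_distance(c(0), c(3, 4))[1, ], c(9, 16))
  A <- matrix(c(0, 0), 1, 2)
  B <- matrix(c(3, 4), 1, 2)
  expect_identical(pairwise_distance(A, B)[1, 1], 25)
  expect_identical(pairwise_distance(A, B, "euclidean")[1, 1], 5)
  expect_identical(pairwise_distance(A, A)[1, 1], 0)

  withr::with_seed(1, {
    X <- matrix(rnorm(20 * 4), 20, 4)
    Y <- matrix(rnorm(20 * 4), 20, 4)
    for (metric in c("squared_euclidean", "euclidean")) {
      D <- pairwise_distance(X, Y, metric)
      ref <- matrix(0, 20, 20)
      for (i in 1:20) for (j in 1:20) ref[i, j] <- oracle_dist(X[i, ], Y[j, ], metric)
      expect_equal(D, ref, tolerance = 1e-12)
      S <- pairwise_distance(X, X, metric)
      expect_equal(S, t(S), tolerance = 1e-12)
      expect_equal(max(abs(diag(S))), 0, tolerance = 1e-12)
    }
  })
  expect_error(pairwise_distance(matrix(0, 1, 2), matrix(0, 1, 3)),
               class = "deeplof_argument_error")
})

test_that("k-distance neighborhoods include ties and use exhaustive search", {
  # line {0, 10, 30, 40}, query 20, k = 2 (the query is not a reference)
  expect_setequal(k_distance_neighborhood(20, c(0, 10, 30, 40), k = 2), c(2, 3))
  # query coincident with one reference, k = 1: that reference at distance 0
  expect_identical(k_distance_neighborhood(10, c(0, 10, 30), k = 1), 2L)
  # three equidistant nearest points with k = 2: neighborhood of size 3
  refs <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(5, 5))
  expect_length(k_distance_neighborhood(c(0, 0), refs, k = 2), 3)
  expect_error(k_distance_neighborhood(0, c(1, 2), k = 2),
               class = "deeplof_argument_error")
})

test_that("lrd reproduces the worked line examples and is homogeneous", {
  refs <- c(0, 10, 20, 30, 40)
  expect_equal(lrd(20, refs, k = 2), 1 / 100)
  expect_equal(lrd(100, refs, k = 2), 1 / 4250)   # mean of 3600, 4900
  # squared distances scale with c^2, so lrd scales with 1/c^2
  for (c_scale in c(2, 7)) {
    expect_equal(lrd(100 * c_scale, refs * c_scale, k = 2),
                 (1 / 4250) / c_scale^2)
  }
})

test_that("LOF reproduces the worked line examples", {
  refs <- c(0, 10, 20, 30, 40)
  expect_equal(lof_score(20, refs, k = 2), 1.0)
  expect_equal(lof_score(100, refs, k = 2), 29.75)
  expect_identical(classify_scores(c(1.0, 29.75), threshold = 2),
                   c("normal", "abnormal"))
})

test_that("both variants match the independent brute-force oracle", {
  withr::with_seed(11, {
    for (i in 1:40) {
      n <- sample(8:40, 1)
      d <- sample(1:6, 1)
      k <- sample(1:min(5, n - 2), 1)
      X <- matrix(round(rnorm(n * d), 2), n, d)   # rounding induces ties
      p <- if (runif(1) < 0.3) X[sample(n, 1), ] else round(rnorm(d), 2)
      metric <- sample(c("squared_euclidean", "euclidean"), 1)
      variant <- sample(c("raw", "reachability"), 1)
      got <- lof_score(p, X, k = k, metric = metric, variant = variant)
      want <- oracle_lof(p, X, k = k, metric = metric, variant = variant)
      expect_equal(got, want, tolerance = 1e-10)
    }
  })
})

test_that("LOF is invariant under translation and rotation", {
  withr::with_seed(12, {
    X <- matrix(rnorm(30 * 2), 30, 2)
    p <- c(2.5, -1)
    theta <- 0.83
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    shift <- c(5, -3)
    Xt <- sweep(X %*% R, 2, shift, "+")
    pt <- drop(p %*% R) + shift
    for (variant in c("raw", "reachability")) {
      expect_equal(lof_score(pt, Xt, k = 4, variant = variant),
                   lof_score(p, X, k = 4, variant = variant),
                   tolerance = 1e-9)
    }
  })
})

test_that("interior lattice points score close to 1", {
  grid <- as.matrix(expand.grid(x = 1:20, y = 1:20))
  model <- lof_fit(grid, k = 5, variant = "reachability")
  interior <- grid[grid[, 1] %in% 8:13 & grid[, 2] %in% 8:13, ]
  s <- predict(model, interior)$lof
  expect_true(all(abs(s - 1) < 0.1))
  model_p <- lof_fit(grid, k = 5, variant = "raw")
  sp <- predict(model_p, interior)$lof
  expect_true(all(abs(sp - 1) < 0.1))
})

test_that("LOF increases monotonically as a query escapes a cluster", {
  withr::with_seed(13, {
    X <- matrix(rnorm(40 * 2, sd = 0.5), 40, 2)
    dists <- c(3, 5, 8, 13, 21)
    s <- vapply(dists, function(r) lof_score(c(r, 0), X, k = 5), numeric(1))
    expect_true(all(diff(s) > 0))
  })
})

test_that("fitted scoring matches the standalone computation and its contracts", {
  withr::with_seed(14, {
    X <- matrix(rnorm(25 * 3), 25, 3)
    q <- matrix(rnorm(5 * 3), 5, 3)
    for (variant in c("raw", "reachability")) {
      model <- lof_fit(X, k = 5, variant = variant)
      got <- predict(model, q)$lof
      want <- vapply(seq_len(5), function(i) {
        lof_score(q[i, ], X, k = 5, variant = variant)
      }, numeric(1))
      expect_equal(got, want, tolerance = 1e-12)

      # leave-one-out on a training reference is finite
      self_scores <- predict(model, X[1:3, ])$lof
      expect_true(all(is.finite(self_scores)))

      # permuting the references leaves scores unchanged
      perm <- sample(25)
      model_p <- lof_fit(X[perm, ], k = 5, variant = variant)
      expect_equal(predict(model_p, q)$lof, got, tolerance = 1e-12)
    }
  })
})

test_that("far queries score higher than central ones", {
  withr::with_seed(15, {
    X <- matrix(rnorm(60 * 2), 60, 2)
    model <- lof_fit(X, k = 5)
    center <- colMeans(X)
    far <- predict(model, rbind(center + 40))$lof
    near <- predict(model, rbind(center))$lof
    expect_gt(far, near)
    expect_gt(far, 2)
  })
})

test_that("duplicates of an infinitely dense spot are not outliers", {
  refs <- rbind(matrix(1, 4, 2), c(9, 9), c(-9, 9), c(0, -9))
  # query duplicates the 4x-repeated point: all k=3 neighbors at distance 0
  expect_identical(lof_score(c(1, 1), refs, k = 3), 1)
})

test_that("reference filtering follows fit_scope and include_textures", {
  feats <- tibble::tibble(
    case_id = sprintf("c%d", 1:9),
    label = rep(c(0L, 1L, 2L), each = 3),
    x_1 = rnorm(9), x_2 = rnorm(9)
  )
  m_norm <- lof_fit(feats, k = 2, fit_scope = "normal_only")
  expect_identical(nrow(m_norm$refs), 3L)
  m_all <- lof_fit(feats, k = 2, fit_scope = "all_cohort")
  expect_identical(nrow(m_all$refs), 6L)
  m_tex <- lof_fit(feats, k = 2, fit_scope = "normal_only", include_textures = TRUE)
  expect_identical(nrow(m_tex$refs), 6L)
  expect_error(lof_fit(matrix(rnorm(8), 4, 2), k = 5),
               class = "deeplof_argument_error")
})

test_that("thresholding sentinels behave", {
  s <- c(0.4, 1.2, 7)
  expect_identical(classify_scores(s, Inf), rep("normal", 3))
  expect_identical(classify_scores(s, 0), rep("abnormal", 3))
  tb <- classify_scores(tibble::tibble(case_id = "a", label = 1L, lof = 3), 2)
  expect_identical(tb$decision, "abnormal")
})
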