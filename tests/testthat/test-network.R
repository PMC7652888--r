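test_that("l2_constrain rescales onto the alpha-sphere", {
  expect_equal(l2_constrain(c(3, 4), alpha = 80), c(48, 64))
  x <- c(48, 64)   # already at norm 80
  expect_equal(l2_constrain(x, 80), x, tolerance = 1e-6)
  withr::with_seed(1, {
    for (i in 1:20) {
      v <- rnorm(sample(2:50, 1))
      expect_equal(sqrt(sum(l2_constrain(v, 80)^2)), 80, tolerance = 1e-9)
      # scale invariance in the input
      expect_equal(l2_constrain(3.7 * v, 80), l2_constrain(v, 80), tolerance = 1e-9)
    }
  })
})

test_that("zero vectors are degenerate unless an epsilon guard is requested", {
  expect_error(l2_constrain(c(0, 0), 80), class = "deeplof_argument_error")
  expect_identical(l2_constrain(c(0, 0), 80, eps = 1e-12), c(0, 0))
})

test_that("the constrained softmax loss matches closed forms", {
  # uniform softmax: W = 0, b = 0 -> loss = log C
  head <- list(W = matrix(0, 4, 3), b = numeric(3))
  f <- l2_constrain(rnorm(4), 80)
  expect_equal(l2_softmax_loss(f, 0L, head), log(3))

  # logits (10, 0, 0), label 0 -> log(1 + 2 exp(-10))
  head2 <- list(W = matrix(c(10, 0, 0), 1, 3), b = numeric(3))
  expect_equal(l2_softmax_loss(matrix(1), 0L, head2), log(1 + 2 * exp(-10)))

  # a one-hot soft label reduces exactly to the hard-label loss
  withr::with_seed(2, {
    feats <- matrix(rnorm(6), 2, 3)
    head3 <- list(W = matrix(rnorm(9), 3, 3), b = rnorm(3))
    soft <- rbind(c(0, 1, 0), c(1, 0, 0))
    expect_identical(l2_softmax_loss(feats, soft, head3),
                     l2_softmax_loss(feats, c(1L, 0L), head3))
  })
  expect_error(l2_softmax_loss(matrix(1), 3L, head2), class = "deeplof_argument_error")
  expect_error(l2_softmax_loss(matrix(1), matrix(c(0.5, 0.2, 0.1), 1), head2),
               class = "deeplof_argument_error")
})

test_that("head gradients match central finite differences", {
  withr::with_seed(3, {
    feats <- matrix(rnorm(8), 2, 4)
    head <- list(W = matrix(rnorm(12, sd = 0.3), 4, 3), b = rnorm(3, sd = 0.1))
    labels <- c(1L, 2L)
    g <- l2_softmax_loss_grad(feats, labels, head)
    eps <- 1e-6
    for (j in seq_along(head$W)) {
      hp <- head; hp$W[j] <- hp$W[j] + eps
      hm <- head; hm$W[j] <- hm$W[j] - eps
      num <- (l2_softmax_loss(feats, labels, hp) -
                l2_softmax_loss(feats, labels, hm)) / (2 * eps)
      expect_equal(g$dW[j], num, tolerance = 1e-4)
    }
    for (j in seq_along(head$b)) {
      hp <- head; hp$b[j] <- hp$b[j] + eps
      hm <- head; hm$b[j] <- hm$b[j] - eps
      num <- (l2_softmax_loss(feats, labels, hp) -
                l2_softmax_loss(feats, labels, hm)) / (2 * eps)
      expect_equal(g$db[j], num, tolerance = 1e-4)
    }
  })
})

test_that("tiny_cnn forward produces simplex outputs and alpha-norm features", {
  tc <- training_config(backbone = "tiny_cnn", input_size = 16L,
                        feature_width = 8L, seed = 5)
  model <- build_model(tc, l2_head_config(alpha = 80, n_classes = 3))
  withr::with_seed(6, {
    for (i in 1:5) {
      x <- array(runif(16 * 16 * 3), c(16, 16, 3))
      fw <- deeplof:::nn_forward(model, x)
      p <- deeplof:::softmax_probs(fw$logits)
      expect_length(p, 3)
      expect_equal(sum(p), 1, tolerance = 1e-6)
      expect_equal(sqrt(sum(fw$feature^2)), 80, tolerance = 80 * 1e-5)
    }
  })
  # descriptor dimension equals the configured penultimate width
  expect_identical(model$feature_dim, 8L)
})

test_that("freezing marks the first weight-bearing layers non-trainable", {
  tc <- training_config(backbone = "tiny_cnn", input_size = 16L,
                        feature_width = 8L, frozen_layers = 2L, seed = 1)
  model <- build_model(tc, l2_head_config())
  ls <- layer_summary(model)
  expect_identical(ls$trainable, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # over-freezing clamps below the classifier
  tc$frozen_layers <- 99L
  expect_warning(m2 <- build_model(tc, l2_head_config()), "clamping")
  expect_identical(sum(layer_summary(m2)$trainable), 1L)
})

test_that("vgg16 topology freezes exactly its first 10 weight-bearing layers", {
  tc <- training_config(backbone = "vgg16_transfer", input_size = 32L, seed = 1)
  model <- build_model(tc, l2_head_config(alpha = 80, n_classes = 3))
  ls <- layer_summary(model)
  expect_identical(nrow(ls), 16L)          # 13 conv + 2 dense + classifier
  expect_identical(sum(!ls$trainable), 10L)
  expect_true(all(!ls$trainable[1:10]))    # counted from the input
  expect_true(all(ls$trainable[11:16]))
  expect_identical(model$feature_dim, 4096L)
})

test_that("training reduces loss, freezes weights bitwise, and is seed-deterministic", {
  toy <- toy_class_images(n_per_class = 5, size = 16)
  cases <- toy_cases(toy, c(0L, 1L))
  textures <- toy_textures(toy)
  tc <- training_config(backbone = "tiny_cnn", input_size = 16L,
                        feature_width = 8L, learning_rate = 1e-3,
                        max_epochs = 12L, early_stop_patience = 12L,
                        frozen_layers = 1L, seed = 7)
  model <- build_model(tc, l2_head_config(alpha = 80, n_classes = 3))
  frozen_before <- model$layers[[1]]$W
  trained <- train_model(model, cases[1:8], cases[9:10],
                         textures = textures, augment = augment_none(),
                         config = tc)
  hist <- trained$history
  expect_lt(hist$train_loss[nrow(hist)], hist$train_loss[1])
  expect_identical(trained$layers[[1]]$W, frozen_before)    # frozen bitwise
  expect_lte(nrow(hist), tc$max_epochs)
  expect_identical(trained$best_epoch, which.min(hist$val_loss))

  trained2 <- train_model(build_model(tc, l2_head_config(alpha = 80, n_classes = 3)),
                          cases[1:8], cases[9:10], textures = textures,
                          augment = augment_none(), config = tc)
  expect_identical(trained$layers[[5]]$W, trained2$layers[[5]]$W)
})

test_that("zero patience stops as soon as validation loss stalls", {
  toy <- toy_class_images(n_per_class = 4, size = 16)
  cases <- toy_cases(toy, c(0L, 1L))
  # validation cases carry flipped labels: fitting the training set drives
  # the validation loss up, so it never improves after the first epochs
  flipped <- purrr::map(cases[7:8], function(cs) {
    cs$label <- 1L - cs$label
    cs
  })
  tc <- training_config(backbone = "tiny_cnn", input_size = 16L,
                        feature_width = 4L, learning_rate = 1e-3,
                        max_epochs = 30L, early_stop_patience = 0L, seed = 8)
  model <- build_model(tc, l2_head_config(alpha = 80, n_classes = 2))
  trained <- train_model(model, cases[1:6], flipped,
                         augment = augment_none(), config = tc)
  hist <- trained$history
  expect_lt(nrow(hist), 30)
  expect_identical(trained$best_epoch, which.min(hist$val_loss))
})

test_that("feature extraction returns alpha-norm descriptors, duplicates identical", {
  toy <- toy_class_images(n_per_class = 4, size = 16)
  cases <- toy_cases(toy, c(0L, 1L))
  tc <- training_config(backbone = "tiny_cnn", input_size = 16L,
                        feature_width = 8L, seed = 9)
  model <- build_model(tc, l2_head_config(alpha = 80, n_classes = 3))
  feats <- extract_features(model, c(cases, cases[1]))
  X <- feature_matrix(feats)
  expect_identical(ncol(X), 8L)
  norms <- sqrt(rowSums(X^2))
  expect_true(all(abs(norms - 80) <= 80 * 1e-5))
  expect_identical(unname(X[1, ]), unname(X[nrow(X), ]))   # duplicate input
})

test_that("a trained model separates the toy classes", {
  toy <- toy_class_images(n_per_class = 6, size = 16)
  cases <- toy_cases(toy, c(0L, 1L))
  textures <- toy_textures(toy)
  tc <- training_config(backbone = "tiny_cnn", input_size = 16L,
                        feature_width = 8L, learning_rate = 1e-3,
                        max_epochs = 30L, early_stop_patience = 30L, seed = 10)
  model <- build_model(tc, l2_head_config(alpha = 80, n_classes = 3))
  trained <- train_model(model, cases, cases[1:4], textures = textures,
                         augment = augment_none(), config = tc)
  probs <- predict_softmax(trained, cases)
  pm <- as.matrix(probs[paste0("p_", 0:2)])
  expect_true(all(abs(rowSums(pm) - 1) < 1e-6))
  pred <- max.col(pm) - 1L
  expect_gte(mean(pred == probs$label), 0.9)
  scored <- binary_anomaly_score(probs)
  expect_true(all(scored$score >= 0 & scored$score <= 1))
})

test_that("models round-trip through a checkpoint directory", {
  tc <- training_config(backbone = "tiny_cnn", input_size = 16L,
                        feature_width = 8L, seed = 12)
  model <- build_model(tc, l2_head_config(alpha = 80, n_classes = 3))
  dir <- withr::local_tempdir()
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "weights.rds")))
  back <- load_model(dir)
  x <- array(0.5, c(16, 16, 3))
  expect_identical(deeplof:::nn_forward(back, x)$logits,
                   deeplof:::nn_forward(model, x)$logits)
})
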