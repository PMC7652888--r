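#' L2-norm constraint on a feature vector
#'
#' Rescales a feature descriptor onto the hypersphere of radius `alpha`:
#' `x -> alpha * x / ||x||_2`. Placing all descriptors at a fixed norm
#' turns softmax training into cosine-similarity separation and is the
#' constraint applied to the penultimate-layer activations of the network.
#'
#' @param x Numeric vector with positive norm.
#' @param alpha Target L2 norm (default 80).
#' @param eps Norm guard added to `||x||`; with the default 0, a zero
#'   vector is a degenerate input and raises an error. A small positive
#'   `eps` (as used inside the network layer) returns the zero vector
#'   unchanged in scale.
#' @return Numeric vector with `||result||_2 == alpha` (up to floating
#'   point).
#' @examples
#' l2_constrain(c(3, 4), alpha = 80)  # (48, 64)
#' @export
l2_constrain <- function(x, alpha = 80, eps = 0) {
  check_number(alpha, "alpha", min = .Machine$double.xmin)
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    abort_bad_arg("`x` must be a finite numeric vector.")
  }
  n <- sqrt(sum(x^2))
  if (n == 0 && eps == 0) {
    abort_bad_arg("`x` is the zero vector: its direction is undefined under the L2 constraint.")
  }
  alpha * x / (n + eps)
}

#' Configure the L2-constrained softmax head
#'
#' @param alpha Norm scale of the constraint (default 80); `NULL` disables
#'   the constraint, giving a conventional softmax head.
#' @param n_classes Number of classes `C` (3 for normal/abnormal/texture
#'   training, 2 for the conventional baseline).
#' @return An `l2_head_config` object.
#' @export
l2_head_config <- function(alpha = 80, n_classes = 3L) {
  if (!is.null(alpha)) check_number(alpha, "alpha", min = .Machine$double.xmin)
  check_number(n_classes, "n_classes", min = 2, integerish = TRUE)
  structure(list(alpha = alpha, n_classes = as.integer(n_classes)),
            class = "l2_head_config")
}

#' Configure network training
#'
#' Defaults follow the reference training recipe: Adam at learning rate
#' 1e-5, batch size 1, up to 500 epochs with early stopping on validation
#' loss, 100x100 inputs, and (for the transfer-learning backbone) the first
#' 10 weight-bearing layers frozen. The `tiny_cnn` backbone is a small
#' randomly initialised network for desk-scale work that needs no
#' pretrained weights; it defaults to no frozen layers.
#'
#' @param backbone `"tiny_cnn"` or `"vgg16_transfer"`.
#' @param learning_rate Adam learning rate.
#' @param batch_size Gradient accumulation size (the reference recipe uses 1).
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (best weights are restored).
#' @param frozen_layers Number of weight-bearing layers, counted from the
#'   input, whose parameters are not updated; `NULL` means the backbone
#'   default (10 for `vgg16_transfer`, 0 for `tiny_cnn`).
#' @param input_size Network input side length in pixels.
#' @param feature_width Width of the penultimate (feature) layer of
#'   `tiny_cnn`.
#' @param weights_path Optional path to an `.rds` file with pretrained
#'   weights for `vgg16_transfer` (list of `list(W, b)` per weight-bearing
#'   layer); without it the topology is randomly initialised.
#' @param seed Integer seed controlling initialisation and the training
#'   loop.
#' @return A `training_config` object.
#' @export
training_config <- function(backbone = c("tiny_cnn", "vgg16_transfer"),
                            learning_rate = 1e-5, batch_size = 1L,
                            max_epochs = 500L, early_stop_patience = 20L,
                            frozen_layers = NULL, input_size = 100L,
                            feature_width = 64L, weights_path = NULL,
                            seed = 1L) {
  backbone <- match.arg(backbone)
  check_number(learning_rate, "learning_rate", min = .Machine$double.xmin)
  check_number(batch_size, "batch_size", min = 1, integerish = TRUE)
  check_number(max_epochs, "max_epochs", min = 1, integerish = TRUE)
  check_number(early_stop_patience, "early_stop_patience", min = 0, integerish = TRUE)
  check_number(input_size, "input_size", min = 8, integerish = TRUE)
  check_number(feature_width, "feature_width", min = 2, integerish = TRUE)
  if (is.null(frozen_layers)) {
    frozen_layers <- if (backbone == "vgg16_transfer") 10L else 0L
  }
  check_number(frozen_layers, "frozen_layers", min = 0, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(backbone = backbone, optimizer = "adam",
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         frozen_layers = as.integer(frozen_layers),
         input_size = as.integer(input_size),
         feature_width = as.integer(feature_width),
         weights_path = weights_path, seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Softmax cross-entropy on L2-constrained feature descriptors
#'
#' Mean cross-entropy `-(1/M) sum_i log softmax(W'f(x_i) + b)[y_i]` over a
#' batch of feature descriptors, extended to soft labels (e.g. from mixup)
#' by the weighted cross-entropy. The descriptors are expected to already
#' satisfy the norm constraint `||f(x)|| = alpha`.
#'
#' @param features Numeric matrix, one descriptor per row (a single vector
#'   is treated as a one-row batch).
#' @param labels Integer class labels in `0..C-1`, or a matrix of simplex
#'   weight rows.
#' @param head A list or [l2_head_config()]-like object with elements `W`
#'   (d x C weight matrix) and `b` (length-C bias).
#' @return Scalar loss (nonnegative for hard labels).
#' @export
l2_softmax_loss <- function(features, labels, head) {
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  C <- ncol(head$W)
  targets <- label_targets(labels, nrow(features), C)
  logits <- features %*% head$W + matrix(head$b, nrow(features), C, byrow = TRUE)
  total <- 0
  for (i in seq_len(nrow(features))) {
    total <- total + softmax_ce(logits[i, ], targets[i, ])$loss
  }
  total / nrow(features)
}

#' Gradient of the L2-constrained softmax loss w.r.t. the head
#'
#' Analytic gradient of [l2_softmax_loss()] with respect to the classifier
#' weights and bias; exposed so it can be verified against finite
#' differences.
#'
#' @inheritParams l2_softmax_loss
#' @return List with elements `dW` (d x C) and `db` (length C).
#' @export
l2_softmax_loss_grad <- function(features, labels, head) {
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  C <- ncol(head$W)
  M <- nrow(features)
  targets <- label_targets(labels, M, C)
  logits <- features %*% head$W + matrix(head$b, M, C, byrow = TRUE)
  dW <- head$W * 0
  db <- numeric(C)
  for (i in seq_len(M)) {
    dz <- softmax_ce(logits[i, ], targets[i, ])$dlogits
    dW <- dW + outer(features[i, ], dz)
    db <- db + dz
  }
  list(dW = dW / M, db = db / M)
}

label_targets <- function(labels, M, C) {
  if (is.matrix(labels)) {
    if (nrow(labels) != M || ncol(labels) != C) {
      abort_bad_arg("soft-label matrix must be M x C.")
    }
    if (any(labels < -1e-9) || any(abs(rowSums(labels) - 1) > 1e-6)) {
      abort_bad_arg("soft labels must be nonnegative simplex rows.")
    }
    return(labels)
  }
  labels <- as.integer(labels)
  if (length(labels) != M) abort_bad_arg("`labels` must match the batch size.")
  if (any(labels < 0L | labels >= C)) {
    abort_bad_arg(sprintf("labels must lie in 0..%d.", C - 1L))
  }
  t(vapply(labels, function(l) {
    w <- numeric(C); w[l + 1L] <- 1; w
  }, numeric(C)))
}

vgg16_conv_plan <- list(
  c(64, 64), c(128, 128), c(256, 256, 256), c(512, 512, 512), c(512, 512, 512)
)

#' Build an untrained classification model
#'
#' Constructs the sequential network for the chosen backbone, ending in the
#' L2-constraint layer (when `head$alpha` is set) followed by the C-way
#' softmax classifier. `tiny_cnn` is three conv/ReLU/maxpool blocks, global
#' average pooling and a dense feature layer; `vgg16_transfer` is the
#' standard 13-conv VGG16 topology with two 4096-wide dense layers, its
#' first `frozen_layers` weight-bearing layers frozen, and conv weights
#' loaded from `config$weights_path` when provided.
#'
#' @param config A [training_config()].
#' @param head An [l2_head_config()].
#' @return A `dcnn_model` object.
#' @export
build_model <- function(config = training_config(), head = l2_head_config()) {
  S <- config$input_size
  C <- head$n_classes
  withr::with_seed(derive_seed(config$seed, 5L), {
    layers <- list()
    h <- S; w <- S; c_in <- 3L
    add <- function(l) layers[[length(layers) + 1L]] <<- l
    if (config$backbone == "tiny_cnn") {
      for (n_f in c(8L, 16L, 32L)) {
        add(nn_layer_conv(h, w, c_in, n_f))
        add(list(type = "relu"))
        add(list(type = "maxpool"))
        h <- h %/% 2L; w <- w %/% 2L; c_in <- n_f
      }
      add(list(type = "gap"))
      add(nn_layer_dense(c_in, config$feature_width))
      add(list(type = "relu"))
      feat_dim <- config$feature_width
    } else {
      for (block in vgg16_conv_plan) {
        for (n_f in block) {
          add(nn_layer_conv(h, w, c_in, n_f))
          add(list(type = "relu"))
          c_in <- n_f
        }
        add(list(type = "maxpool"))
        h <- h %/% 2L; w <- w %/% 2L
      }
      add(list(type = "flatten"))
      add(nn_layer_dense(h * w * c_in, 4096L))
      add(list(type = "relu"))
      add(nn_layer_dense(4096L, 4096L))
      add(list(type = "relu"))
      feat_dim <- 4096L
    }
    if (!is.null(head$alpha)) {
      add(list(type = "l2norm", alpha = head$alpha, eps = 1e-12))
    }
    add(nn_layer_dense(feat_dim, C, scale = 0.01))
    feature_index <- length(layers) - 1L
    model <- structure(
      list(layers = layers, feature_index = feature_index,
           feature_dim = feat_dim, n_classes = C,
           input_size = S, config = config, head = head,
           history = NULL, best_epoch = NA_integer_),
      class = "dcnn_model"
    )
    if (!is.null(config$weights_path)) {
      model <- load_weights(model, config$weights_path)
    }
    freeze_layers(model, config$frozen_layers)
  })
}

load_weights <- function(model, path) {
  if (!file.exists(path)) {
    abort_bad_arg(sprintf("weights file '%s' not found.", path))
  }
  weights <- readRDS(path)
  wi <- which(vapply(model$layers, function(l) !is.null(l$W), logical(1)))
  for (j in seq_along(weights)) {
    if (j > length(wi) || is.null(weights[[j]])) next
    i <- wi[j]
    if (!identical(dim(model$layers[[i]]$W), dim(weights[[j]]$W))) {
      abort_bad_arg(sprintf("weights entry %d has incompatible dimensions.", j))
    }
    model$layers[[i]]$W <- weights[[j]]$W
    model$layers[[i]]$b <- weights[[j]]$b
  }
  model
}

# Mark the first `n` weight-bearing layers (counted from the input) as not
# trainable. The classifier is never frozen; `n` is clamped below it.
freeze_layers <- function(model, n) {
  wi <- which(vapply(model$layers, function(l) !is.null(l$W), logical(1)))
  n_max <- length(wi) - 1L
  if (n > n_max) {
    rlang::warn(sprintf(
      "frozen_layers = %d exceeds the %d freezable layers of this backbone; clamping.",
      n, n_max))
    n <- n_max
  }
  for (i in wi) model$layers[[i]]$trainable <- TRUE
  for (i in wi[seq_len(n)]) model$layers[[i]]$trainable <- FALSE
  model
}

#' Weight-bearing layers and their trainability
#'
#' @param model A `dcnn_model`.
#' @return Tibble with columns `layer` (index in the sequential stack),
#'   `type`, `n_params`, `trainable`.
#' @export
layer_summary <- function(model) {
  purrr::imap_dfr(model$layers, function(l, i) {
    if (is.null(l$W)) return(NULL)
    tibble::tibble(layer = i, type = l$type,
                   n_params = length(l$W) + length(l$b),
                   trainable = isTRUE(l$trainable))
  })
}

#' @export
print.dcnn_model <- function(x, ...) {
  ls <- layer_summary(x)
  cat(sprintf(
    "<dcnn_model> %s: %d-class head%s, input %dx%dx3, %d weight layers (%s params, %d frozen)%s\n",
    x$config$backbone, x$n_classes,
    if (is.null(x$head$alpha)) "" else sprintf(" with L2 constraint (alpha = %g)", x$head$alpha),
    x$input_size, x$input_size, nrow(ls),
    format(sum(ls$n_params), big.mark = ","), sum(!ls$trainable),
    if (is.null(x$history)) " [untrained]" else sprintf(" [trained, best epoch %d]", x$best_epoch)
  ))
  invisible(x)
}

# Normalise heterogeneous inputs (cases, pseudo-color images, textures,
# raw arrays) into model-ready H x W x 3 arrays with ids and labels.
prepare_inputs <- function(items, input_size, default_label = NA_integer_) {
  out <- purrr::imap(items, function(item, i) {
    if (inherits(item, "grayscale_pair_case")) {
      pc <- fuse_pseudo_color(item)
      list(pixels = resize_to_input(pc$pixels, input_size),
           id = pc$case_id, label = pc$label)
    } else if (inherits(item, "pseudo_color_image")) {
      list(pixels = resize_to_input(item$pixels, input_size),
           id = item$case_id, label = item$label)
    } else if (inherits(item, "texture_image")) {
      img <- item$image
      if (is.matrix(img)) {
        if (all(dim(img) >= input_size)) img <- center_crop(img, input_size)
        img <- resize_to_input(img, input_size)
        img <- array(rep(img, 3L), dim = c(input_size, input_size, 3L))
      } else {
        img <- resize_to_input(img, input_size)
      }
      list(pixels = img, id = item$source_id, label = 2L)
    } else if (is.array(item) && length(dim(item)) == 3L) {
      list(pixels = resize_to_input(item, input_size),
           id = sprintf("img%03d", i), label = default_label)
    } else {
      abort_bad_arg("unsupported input item; expected cases, pseudo-color images, textures or H x W x 3 arrays.")
    }
  })
  list(images = purrr::map(out, "pixels"),
       ids = purrr::map_chr(out, "id"),
       labels = purrr::map_int(out, function(x) as.integer(x$label)))
}

#' Train the classification model
#'
#' Batch-wise gradient training with Adam. Each epoch processes every
#' training pseudo-color image plus (for a 3-class head) every texture
#' image, passed through the augmentation stack; validation loss is
#' computed on the un-augmented validation images after each epoch.
#' Training stops at `max_epochs` or once the validation loss has not
#' improved for `early_stop_patience` consecutive epochs; the weights of
#' the best-validation-loss epoch are restored.
#'
#' @param model A `dcnn_model` from [build_model()].
#' @param train_cases,val_cases Lists of `grayscale_pair_case` (or
#'   pseudo-color images); `val_cases` must be nonempty.
#' @param textures Optional list of `texture_image` objects trained as
#'   class 2 (requires a 3-class head).
#' @param augment An [augment_config()]; `NULL` disables augmentation.
#' @param config A [training_config()]; defaults to the one stored in the
#'   model.
#' @return The trained `dcnn_model`, with `$history` (tibble of epoch,
#'   train_loss, val_loss) and `$best_epoch`.
#' @export
train_model <- function(model, train_cases, val_cases, textures = NULL,
                        augment = augment_config(), config = NULL) {
  config <- config %||% model$config
  if (length(train_cases) == 0L) abort_bad_arg("`train_cases` must be nonempty.")
  if (length(val_cases) == 0L) abort_bad_arg("`val_cases` must be nonempty.")
  if (!is.null(textures) && length(textures) > 0 && model$n_classes < 3L) {
    abort_bad_arg("texture images require a 3-class head.")
  }
  augment <- augment %||% augment_none()

  tr <- prepare_inputs(c(train_cases, textures %||% list()), model$input_size)
  va <- prepare_inputs(val_cases, model$input_size)
  C <- model$n_classes
  if (any(tr$labels >= C) || any(va$labels >= C)) {
    abort_bad_arg("a training label exceeds the number of classes in the head.")
  }

  state <- nn_init_adam(model)
  t_step <- 0L
  best_val <- Inf
  best_snapshot <- nn_snapshot_weights(model)
  best_epoch <- 0L
  wait <- 0L
  history <- vector("list", config$max_epochs)

  val_loss_of <- function(m) {
    losses <- purrr::map2_dbl(va$images, va$labels, function(img, lab) {
      target <- numeric(C); target[lab + 1L] <- 1
      softmax_ce(nn_forward(m, img)$logits, target)$loss
    })
    mean(losses)
  }

  for (epoch in seq_len(config$max_epochs)) {
    stream <- augment_epoch(tr$images, tr$labels, augment,
                            seed = derive_seed(config$seed, 100L + epoch),
                            n_classes = C)
    ord <- withr::with_seed(derive_seed(config$seed, 7000L + epoch),
                            sample(seq_along(stream)))
    ep_losses <- numeric(length(stream))
    acc <- NULL
    n_acc <- 0L
    for (pos in seq_along(ord)) {
      item <- stream[[ord[pos]]]
      fw <- nn_forward(model, item$pixels, want_cache = TRUE)
      ce <- softmax_ce(fw$logits, item$label_weights)
      ep_losses[pos] <- ce$loss
      grads <- nn_backward(model, fw$caches, ce$dlogits)
      acc <- if (is.null(acc)) grads else accumulate_grads(acc, grads)
      n_acc <- n_acc + 1L
      if (n_acc == config$batch_size || pos == length(ord)) {
        acc <- scale_grads(acc, 1 / n_acc)
        t_step <- t_step + 1L
        upd <- nn_adam_step(model, state, acc, config$learning_rate, t_step)
        model <- upd$model
        state <- upd$state
        acc <- NULL
        n_acc <- 0L
      }
    }
    vl <- val_loss_of(model)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(ep_losses), val_loss = vl
    )
    if (vl < best_val - 1e-12) {
      best_val <- vl
      best_snapshot <- nn_snapshot_weights(model)
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$early_stop_patience) break
    }
  }

  model <- nn_restore_weights(model, best_snapshot)
  model$history <- dplyr::bind_rows(history)
  model$best_epoch <- best_epoch
  model
}

accumulate_grads <- function(a, b) {
  purrr::map2(a, b, function(x, y) {
    if (is.null(x)) return(NULL)
    list(W = x$W + y$W, b = x$b + y$b)
  })
}

scale_grads <- function(g, s) {
  purrr::map(g, function(x) {
    if (is.null(x)) return(NULL)
    list(W = x$W * s, b = x$b * s)
  })
}

#' Extract penultimate-layer feature descriptors
#'
#' Runs the forward pass and collects the activation of the feature layer
#' (the L2-constrained penultimate layer when the constraint is part of the
#' head, so every descriptor has L2 norm `alpha`).
#'
#' @param model A trained (or untrained) `dcnn_model`.
#' @param items List of cases / pseudo-color images / textures / arrays.
#' @return A tibble with columns `case_id`, `label`, and `x_1 .. x_d`
#'   feature columns.
#' @export
extract_features <- function(model, items) {
  inp <- prepare_inputs(items, model$input_size)
  feats <- t(vapply(inp$images,
                    function(img) nn_forward(model, img)$feature,
                    numeric(model$feature_dim)))
  colnames(feats) <- paste0("x_", seq_len(ncol(feats)))
  dplyr::bind_cols(
    tibble::tibble(case_id = inp$ids, label = inp$labels),
    tibble::as_tibble(feats)
  )
}

#' Matrix view of a feature tibble
#'
#' @param features Tibble from [extract_features()] (columns `x_1..x_d`).
#' @return Numeric matrix, one descriptor per row, rownames = case ids.
#' @export
feature_matrix <- function(features) {
  m <- as.matrix(features[grep("^x_", names(features), value = TRUE)])
  rownames(m) <- features$case_id
  m
}

#' Class-probability predictions
#'
#' @param model A `dcnn_model`.
#' @param items List of inputs (see [extract_features()]).
#' @return Tibble with `case_id`, `label` and probability columns
#'   `p_0 .. p_{C-1}` (each row a simplex).
#' @export
predict_softmax <- function(model, items) {
  inp <- prepare_inputs(items, model$input_size)
  probs <- t(vapply(inp$images,
                    function(img) softmax_probs(nn_forward(model, img)$logits),
                    numeric(model$n_classes)))
  colnames(probs) <- paste0("p_", seq_len(ncol(probs)) - 1L)
  dplyr::bind_cols(
    tibble::tibble(case_id = inp$ids, label = inp$labels),
    tibble::as_tibble(probs)
  )
}

#' Binary anomaly score from softmax probabilities
#'
#' Maps a 2- or 3-class probability row to a binary abnormality score: the
#' class-1 probability renormalised over the cohort classes,
#' `p_1 / (p_0 + p_1)`.
#'
#' @param probs Tibble from [predict_softmax()].
#' @return The input tibble with an added `score` column in \[0, 1\].
#' @export
binary_anomaly_score <- function(probs) {
  denom <- probs$p_0 + probs$p_1
  dplyr::mutate(probs, score = ifelse(denom > 0, probs$p_1 / denom, 0.5))
}

#' Save and load a model checkpoint directory
#'
#' `save_model()` writes a checkpoint directory holding the weights
#' (`weights.rds`), a YAML snapshot of the training configuration
#' (`config.yaml`, when the yaml package is available), and the training
#' history (`history.csv`). `load_model()` rebuilds the model from the
#' checkpoint.
#'
#' @param model A `dcnn_model`.
#' @param dir Checkpoint directory (created if absent).
#' @return `save_model()` returns `dir` invisibly; `load_model()` returns
#'   the restored `dcnn_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(weights = nn_snapshot_weights(model),
               config = model$config, head = model$head,
               best_epoch = model$best_epoch),
          file.path(dir, "weights.rds"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(list(training = unclass(model$config),
                          head = unclass(model$head)),
                     file.path(dir, "config.yaml"))
  }
  if (!is.null(model$history)) {
    utils::write.csv(model$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  snap <- readRDS(file.path(dir, "weights.rds"))
  model <- build_model(snap$config, snap$head)
  model <- nn_restore_weights(model, snap$weights)
  hist_path <- file.path(dir, "history.csv")
  if (file.exists(hist_path)) {
    model$history <- tibble::as_tibble(utils::read.csv(hist_path))
  }
  model$best_epoch <- snap$best_epoch
  model
}
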