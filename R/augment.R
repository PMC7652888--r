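#' Configure the training-time augmentation stack
#'
#' Controls the per-epoch augmentation applied to every training image:
#' vertical/horizontal flips, uniform rotation, random erasing and mixup.
#' Defaults for random erasing follow the technique's original convention
#' (probability 0.5, erased area 2--33% of the image, aspect ratio
#' 0.3--3.3); `mixup_alpha` defaults to 0.2.
#'
#' @param p_hflip,p_vflip Probability of a horizontal / vertical flip.
#' @param rotation_range Maximum absolute rotation in degrees; the angle is
#'   drawn uniformly from `[-rotation_range, rotation_range]` (default 180).
#' @param erase_prob Probability of applying random erasing.
#' @param erase_area_range Length-2 fraction-of-image-area range of the
#'   erased rectangle.
#' @param erase_aspect_range Length-2 aspect-ratio range of the erased
#'   rectangle.
#' @param mixup Logical; apply mixup pairing within the epoch stream.
#' @param mixup_alpha Beta-distribution shape for the mixup weight.
#' @param mixup_scope `"all"` pairs any two stream items (cohort and
#'   texture classes mix); `"cohort_only"` restricts partners to cohort
#'   images.
#' @return An `augment_config` object.
#' @export
augment_config <- function(p_hflip = 0.5, p_vflip = 0.5, rotation_range = 180,
                           erase_prob = 0.5, erase_area_range = c(0.02, 0.33),
                           erase_aspect_range = c(0.3, 3.3),
                           mixup = TRUE, mixup_alpha = 0.2,
                           mixup_scope = c("all", "cohort_only")) {
  check_probability(p_hflip, "p_hflip")
  check_probability(p_vflip, "p_vflip")
  check_number(rotation_range, "rotation_range", min = 0, max = 360)
  check_probability(erase_prob, "erase_prob")
  if (length(erase_area_range) != 2 || any(erase_area_range <= 0) ||
      any(erase_area_range >= 1) || erase_area_range[1] > erase_area_range[2]) {
    abort_bad_arg("`erase_area_range` must be an increasing pair in (0, 1).")
  }
  if (length(erase_aspect_range) != 2 || any(erase_aspect_range <= 0) ||
      erase_aspect_range[1] > erase_aspect_range[2]) {
    abort_bad_arg("`erase_aspect_range` must be an increasing positive pair.")
  }
  check_number(mixup_alpha, "mixup_alpha", min = 1e-12)
  structure(
    list(p_hflip = p_hflip, p_vflip = p_vflip, rotation_range = rotation_range,
         erase_prob = erase_prob, erase_area_range = erase_area_range,
         erase_aspect_range = erase_aspect_range,
         mixup = isTRUE(mixup), mixup_alpha = mixup_alpha,
         mixup_scope = match.arg(mixup_scope)),
    class = "augment_config"
  )
}

#' Disable all augmentations
#'
#' Convenience constructor for an identity augmentation stack.
#' @return An `augment_config` with every augmentation turned off.
#' @export
augment_none <- function() {
  augment_config(p_hflip = 0, p_vflip = 0, rotation_range = 0,
                 erase_prob = 0, mixup = FALSE)
}

flip_h <- function(image) {
  if (is.matrix(image)) image[, ncol(image):1]
  else image[, dim(image)[2]:1, , drop = FALSE]
}

flip_v <- function(image) {
  if (is.matrix(image)) image[nrow(image):1, ]
  else image[dim(image)[1]:1, , , drop = FALSE]
}

rotate_image <- function(image, angle) {
  if (abs(angle) < 1e-12) return(image)
  rot_one <- function(m) {
    clip01(as.matrix(EBImage::rotate(m, angle, output.dim = dim(m), bg.col = 0)))
  }
  if (is.matrix(image)) return(rot_one(image))
  out <- image
  for (ch in seq_len(dim(image)[3])) out[, , ch] <- rot_one(image[, , ch])
  out
}

#' Random flip and rotation
#'
#' Applies a horizontal flip with probability `p_hflip`, a vertical flip
#' with probability `p_vflip`, then a rotation about the image center by an
#' angle drawn uniformly from `[-rotation_range, rotation_range]` degrees
#' (bilinear, corners exposed by the rotation filled with zeros). Uses the
#' current R random number stream.
#'
#' @param image Matrix or H x W x C array in \[0, 1\].
#' @param config An [augment_config()].
#' @return Augmented image, same shape, values in \[0, 1\].
#' @export
random_flip_rotate <- function(image, config) {
  check_pixels(image)
  if (config$p_hflip > 0 && stats::runif(1) < config$p_hflip) image <- flip_h(image)
  if (config$p_vflip > 0 && stats::runif(1) < config$p_vflip) image <- flip_v(image)
  if (config$rotation_range > 0) {
    angle <- stats::runif(1, -config$rotation_range, config$rotation_range)
    image <- rotate_image(image, angle)
  }
  image
}

#' Random erasing
#'
#' With probability `erase_prob`, overwrites one axis-aligned rectangle
#' (area and aspect ratio drawn from the configured ranges) with
#' independent uniform noise in \[0, 1\]; otherwise returns the image
#' unchanged. Uses the current R random number stream.
#'
#' @inheritParams random_flip_rotate
#' @return Image of the same shape.
#' @export
random_erasing <- function(image, config) {
  check_pixels(image)
  if (config$erase_prob <= 0 || stats::runif(1) >= config$erase_prob) return(image)
  d <- dim(image)
  h <- d[1]; w <- d[2]
  for (attempt in 1:100) {
    area <- stats::runif(1, config$erase_area_range[1], config$erase_area_range[2]) * h * w
    aspect <- stats::runif(1, config$erase_aspect_range[1], config$erase_aspect_range[2])
    eh <- round(sqrt(area * aspect))
    ew <- round(sqrt(area / aspect))
    if (eh >= 1 && ew >= 1 && eh <= h && ew <= w) {
      r0 <- sample.int(h - eh + 1L, 1L) - 1L
      c0 <- sample.int(w - ew + 1L, 1L) - 1L
      rows <- (r0 + 1):(r0 + eh)
      cols <- (c0 + 1):(c0 + ew)
      if (is.matrix(image)) {
        image[rows, cols] <- stats::runif(eh * ew)
      } else {
        image[rows, cols, ] <- stats::runif(eh * ew * d[3])
      }
      return(image)
    }
  }
  image
}

new_soft_labeled_image <- function(pixels, label_weights) {
  structure(list(pixels = pixels, label_weights = label_weights),
            class = "soft_labeled_image")
}

#' Mixup of two soft-labeled images
#'
#' Forms the convex combination `lambda * a + (1 - lambda) * b` of both the
#' pixels and the label weights. When `lambda` is omitted it is drawn from
#' `Beta(mixup_alpha, mixup_alpha)`.
#'
#' @param a,b `soft_labeled_image` objects (fields `pixels`,
#'   `label_weights` on the probability simplex) with identical shapes.
#' @param lambda Mixing weight in \[0, 1\]; drawn from the Beta
#'   distribution when `NULL`.
#' @param mixup_alpha Beta shape used when drawing `lambda`.
#' @return A `soft_labeled_image`.
#' @export
mixup <- function(a, b, lambda = NULL, mixup_alpha = 0.2) {
  if (!identical(dim(a$pixels), dim(b$pixels))) {
    abort_bad_arg("mixup inputs must have identical shapes.")
  }
  if (length(a$label_weights) != length(b$label_weights)) {
    abort_bad_arg("mixup inputs must have label weights of equal length.")
  }
  for (w in list(a$label_weights, b$label_weights)) {
    if (any(w < -1e-9) || abs(sum(w) - 1) > 1e-6) {
      abort_bad_arg("label weights must be nonnegative and sum to 1.")
    }
  }
  if (is.null(lambda)) lambda <- stats::rbeta(1, mixup_alpha, mixup_alpha)
  check_probability(lambda, "lambda")
  new_soft_labeled_image(
    lambda * a$pixels + (1 - lambda) * b$pixels,
    lambda * a$label_weights + (1 - lambda) * b$label_weights
  )
}

#' Apply the full augmentation stack to an epoch stream
#'
#' For each item: flip/rotate, then random erasing, then (when enabled)
#' mixup with a random partner from the stream. Deterministic given `seed`;
#' the stream length is preserved and label weights stay on the simplex.
#'
#' @param images List of images (matrices or H x W x C arrays).
#' @param labels Integer class labels (0-based) or a list/matrix of soft
#'   label weight vectors, one per image.
#' @param config An [augment_config()].
#' @param seed Integer seed.
#' @param n_classes Number of classes for one-hot encoding of integer
#'   labels.
#' @return List of `soft_labeled_image` objects, same length as `images`.
#' @export
augment_epoch <- function(images, labels, config, seed = 1L, n_classes = 3L) {
  if (length(images) == 0L) abort_bad_arg("`images` must be a nonempty list.")
  onehot <- function(lab) {
    w <- numeric(n_classes); w[lab + 1L] <- 1; w
  }
  weights <- if (is.list(labels)) labels else lapply(as.integer(labels), onehot)
  if (length(weights) != length(images)) {
    abort_bad_arg("`labels` must match `images` in length.")
  }
  cohort_idx <- which(purrr::map_lgl(weights, function(w) sum(w[seq_len(min(2, length(w)))]) > 0.999))
  withr::with_seed(derive_seed(seed, 4L), {
    base <- purrr::map2(images, weights, function(img, w) {
      img <- random_flip_rotate(img, config)
      img <- random_erasing(img, config)
      new_soft_labeled_image(img, w)
    })
    if (!config$mixup) return(base)
    purrr::imap(base, function(item, i) {
      if (config$mixup_scope == "cohort_only" && !(i %in% cohort_idx)) {
        return(item)   # textures pass through unmixed in cohort-only scope
      }
      pool <- if (config$mixup_scope == "cohort_only") cohort_idx else seq_along(base)
      pool <- setdiff(pool, i)
      if (length(pool) == 0L) return(item)
      partner <- base[[if (length(pool) == 1L) pool else sample(pool, 1L)]]
      mixup(item, partner, mixup_alpha = config$mixup_alpha)
    })
  })
}
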