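# Small fixtures built in code.

tiny_spec <- function(seed = 1L, ...) {
  args <- list(n_normal = 10, n_abnormal = 4, n_textures = 3,
               image_size = 16, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# A linearly separable 3-class toy image set: dark, bright, striped.
toy_class_images <- function(n_per_class = 6, size = 16, seed = 42,
                             n_classes = 3) {
  withr::with_seed(seed, {
    imgs <- list()
    labels <- integer(0)
    stripes <- matrix(rep(c(0.1, 0.9), length.out = size), size, size, byrow = TRUE)
    for (i in seq_len(n_per_class)) {
      for (cls in seq_len(n_classes) - 1L) {
        base <- switch(cls + 1L,
                       matrix(0.15, size, size),
                       matrix(0.85, size, size),
                       stripes)
        m <- pmin(pmax(base + matrix(rnorm(size^2, sd = 0.03), size), 0), 1)
        imgs[[length(imgs) + 1L]] <- array(rep(m, 3), dim = c(size, size, 3))
        labels <- c(labels, cls)
      }
    }
    list(images = imgs, labels = labels)
  })
}

# Wrap toy arrays as pseudo-color-like cases usable by train_model().
toy_cases <- function(toy, which_classes = c(0L, 1L)) {
  keep <- which(toy$labels %in% which_classes)
  purrr::map(keep, function(i) {
    structure(list(pixels = toy$images[[i]],
                   case_id = sprintf("toy%02d", i),
                   label = toy$labels[i]),
              class = "pseudo_color_image")
  })
}

toy_textures <- function(toy) {
  keep <- which(toy$labels == 2L)
  purrr::map(keep, function(i) {
    structure(list(image = toy$images[[i]][, , 1],
                   source_id = sprintf("toytex%02d", i)),
              class = "texture_image")
  })
}

random_scored_set <- function(n1, n0, ties = FALSE, seed = 1) {
  withr::with_seed(seed, {
    pos <- rnorm(n1, mean = 0.8)
    neg <- rnorm(n0)
    if (ties) {
      pool <- round(c(pos, neg), 1)   # heavy ties
      pos <- pool[seq_len(n1)]
      neg <- pool[n1 + seq_len(n0)]
    }
    list(scores = c(pos, neg), labels = rep(c(1, 0), c(n1, n0)))
  })
}
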