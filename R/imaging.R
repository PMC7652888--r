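#' Fuse a grayscale image pair into a pseudo-color image
#'
#' Builds the 3-channel model input from two registered grayscale images:
#' the T1-role image fills the blue channel, the T2-role image the green
#' channel, and the red channel is identically zero. Channel order of the
#' output array is (R, G, B).
#'
#' @param case A `grayscale_pair_case` (fields `img_a` = T1 role, `img_b` =
#'   T2 role, `label`), or a plain list with those fields.
#' @return A `pseudo_color_image`: list with `pixels` (H x W x 3 array in
#'   \[0, 1\]), `case_id`, `label`.
#' @export
fuse_pseudo_color <- function(case) {
  check_pixels(case$img_a, "img_a")
  check_pixels(case$img_b, "img_b")
  if (!identical(dim(case$img_a), dim(case$img_b))) {
    abort_bad_arg("img_a and img_b must have identical height/width.")
  }
  d <- dim(case$img_a)
  px <- array(0, dim = c(d[1], d[2], 3L))
  px[, , 2] <- case$img_b   # green <- T2 role
  px[, , 3] <- case$img_a   # blue  <- T1 role
  structure(
    list(pixels = px, case_id = case$case_id %||% NA_character_,
         label = case$label %||% NA_integer_),
    class = "pseudo_color_image"
  )
}

#' @export
print.pseudo_color_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<pseudo_color_image> %s: %dx%dx%d, label %s\n",
              x$case_id, d[1], d[2], d[3], x$label))
  invisible(x)
}

#' Resize an image to the network input size
#'
#' Bilinear resampling to a square `size` x `size` target; resizing an
#' image already at the target size is the identity.
#'
#' @param image Matrix or H x W x C array in \[0, 1\].
#' @param size Target side length in pixels (default 100, the network
#'   input size).
#' @return Resized image of the same kind (matrix in, matrix out).
#' @export
resize_to_input <- function(image, size = 100) {
  check_number(size, "size", min = 1, integerish = TRUE)
  check_pixels(image)
  resize_one <- function(m) {
    if (all(dim(m) == c(size, size))) return(m)
    clip01(as.matrix(EBImage::resize(m, w = size, h = size)))
  }
  if (is.matrix(image)) return(resize_one(image))
  out <- array(0, dim = c(size, size, dim(image)[3]))
  for (ch in seq_len(dim(image)[3])) out[, , ch] <- resize_one(image[, , ch])
  out
}

#' Center-crop an image
#'
#' Extracts the centered `size` x `size` window with offsets
#' `floor((dim - size) / 2)`; no interpolation is involved.
#'
#' @param image Matrix or H x W x C array.
#' @param size Side length of the crop in pixels.
#' @return The cropped image.
#' @export
center_crop <- function(image, size) {
  check_number(size, "size", min = 1, integerish = TRUE)
  check_pixels(image)
  d <- dim(image)
  if (d[1] < size || d[2] < size) {
    abort_bad_arg(sprintf(
      "image (%dx%d) is smaller than the requested crop (%d); resize first.",
      d[1], d[2], size))
  }
  r0 <- floor((d[1] - size) / 2)
  c0 <- floor((d[2] - size) / 2)
  rows <- (r0 + 1):(r0 + size)
  cols <- (c0 + 1):(c0 + size)
  if (is.matrix(image)) image[rows, cols] else image[rows, cols, , drop = FALSE]
}

# Largest-remainder apportionment of n into parts proportional to fractions.
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits cases into train/val/test preserving the class proportions.
#' Per-class counts follow largest-remainder rounding of `fractions`,
#' unless `explicit_counts` pins the per-class per-split counts exactly
#' (useful to reproduce a published composition table whose rounding
#' differs).
#'
#' @param cases List of `grayscale_pair_case` objects, or a data frame with
#'   columns `case_id` and `label`.
#' @param fractions Length-3 numeric summing to 1: train, val, test.
#' @param seed Integer seed for the random assignment.
#' @param explicit_counts Optional data frame with columns `class`
#'   (`"normal"` / `"abnormal"`), `train`, `val`, `test`; per-class row sums
#'   must match the cohort's class totals.
#' @return A `split_result`: list with character vectors `train`, `val`,
#'   `test` of case ids, plus `fractions` and `seed`.
#' @export
stratified_split <- function(cases, fractions = c(0.6, 0.2, 0.2), seed = 1L,
                             explicit_counts = NULL) {
  manifest <- if (is.data.frame(cases)) tibble::as_tibble(cases) else cohort_manifest(cases)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    abort_bad_arg("`fractions` must be three nonnegative numbers summing to 1.")
  }
  splits <- c("train", "val", "test")
  counts_for <- function(cls, n) {
    if (is.null(explicit_counts)) return(largest_remainder(n, fractions))
    row <- explicit_counts[explicit_counts$class == cls, , drop = FALSE]
    if (nrow(row) != 1L) {
      abort_inconsistent(sprintf("explicit_counts must have one row for class '%s'.", cls))
    }
    cnt <- as.integer(c(row$train, row$val, row$test))
    if (sum(cnt) != n) {
      abort_inconsistent(sprintf(
        "explicit_counts for class '%s' sum to %d but the cohort has %d such cases.",
        cls, sum(cnt), n))
    }
    cnt
  }
  assignment <- withr::with_seed(derive_seed(seed, 3L), {
    purrr::map_dfr(c(normal = 0L, abnormal = 1L), function(lab) {
      ids <- manifest$case_id[manifest$label == lab]
      cls <- if (lab == 1L) "abnormal" else "normal"
      n <- length(ids)
      if (n == 0L) return(tibble::tibble(case_id = character(), split = character()))
      cnt <- counts_for(cls, n)
      shuffled <- sample(ids)
      tibble::tibble(case_id = shuffled, split = rep(splits, times = cnt))
    })
  })
  structure(
    list(
      train = assignment$case_id[assignment$split == "train"],
      val = assignment$case_id[assignment$split == "val"],
      test = assignment$case_id[assignment$split == "test"],
      fractions = fractions, seed = as.integer(seed)
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> train %d / val %d / test %d (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Split assignment as a tibble
#'
#' @param x A `split_result` from [stratified_split()].
#' @param ... Unused.
#' @return Tibble with columns `case_id`, `split`.
#' @export
as_tibble.split_result <- function(x, ...) {
  tibble::tibble(
    case_id = c(x$train, x$val, x$test),
    split = rep(c("train", "val", "test"),
                times = c(length(x$train), length(x$val), length(x$test)))
  )
}
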