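#' Specify a synthetic paired-image cohort
#'
#' Describes the statistical structure of a small, imbalanced two-class
#' cohort of paired grayscale images: a numerous, low-diversity normal class
#' drawn from a handful of shared archetypes, and a rare, high-diversity
#' abnormal class in which each case carries its own random geometry. The
#' defaults mirror a 245-case clinical design with 190 normal (77.6%) and 55
#' abnormal (22.4%) cases and a 61-image auxiliary texture library.
#'
#' @param n_normal,n_abnormal Number of normal / abnormal cases.
#' @param n_textures Number of auxiliary texture images accompanying the
#'   cohort (one per texture material by default).
#' @param image_size Side length in pixels of the square generated images.
#' @param n_archetypes_normal Number of shared archetypes for the normal
#'   class; small values give a compact class.
#' @param n_archetypes_abnormal Number of archetype families for the
#'   abnormal class; each case additionally randomises its geometry, so the
#'   class is diverse. Must be at least `n_archetypes_normal`.
#' @param noise_sd Standard deviation of per-pixel additive Gaussian noise
#'   (intensity units on the \[0, 1\] scale).
#' @param seed Integer seed; identical specs generate bitwise-identical
#'   cohorts.
#'
#' @return A `cohort_spec` object (a named list).
#' @seealso [generate_cohort()], [generate_texture_library()]
#' @export
cohort_spec <- function(n_normal = 190, n_abnormal = 55, n_textures = 61,
                        image_size = 64, n_archetypes_normal = 3,
                        n_archetypes_abnormal = 20, noise_sd = 0.05,
                        seed = 1L) {
  check_number(n_normal, "n_normal", min = 0, integerish = TRUE)
  check_number(n_abnormal, "n_abnormal", min = 0, integerish = TRUE)
  check_number(n_textures, "n_textures", min = 0, integerish = TRUE)
  check_number(image_size, "image_size", min = 8, integerish = TRUE)
  check_number(n_archetypes_normal, "n_archetypes_normal", min = 1, integerish = TRUE)
  check_number(n_archetypes_abnormal, "n_archetypes_abnormal", min = 1, integerish = TRUE)
  if (n_archetypes_abnormal < n_archetypes_normal) {
    abort_bad_arg("`n_archetypes_abnormal` must be >= `n_archetypes_normal` (the abnormal class is the diverse one).")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(
      n_normal = as.integer(n_normal), n_abnormal = as.integer(n_abnormal),
      n_textures = as.integer(n_textures), image_size = as.integer(image_size),
      n_archetypes_normal = as.integer(n_archetypes_normal),
      n_archetypes_abnormal = as.integer(n_archetypes_abnormal),
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d normal + %d abnormal cases (%.1f%% abnormal), %d textures, %dx%d px, seed %d\n",
    x$n_normal, x$n_abnormal,
    if (x$n_normal + x$n_abnormal > 0) 100 * x$n_abnormal / (x$n_normal + x$n_abnormal) else 0,
    x$n_textures, x$image_size, x$image_size, x$seed
  ))
  invisible(x)
}

new_grayscale_pair_case <- function(case_id, img_a, img_b, label) {
  structure(
    list(case_id = case_id, img_a = img_a, img_b = img_b, label = as.integer(label)),
    class = "grayscale_pair_case"
  )
}

#' @export
print.grayscale_pair_case <- function(x, ...) {
  cat(sprintf(
    "<grayscale_pair_case> %s: %dx%d px pair, label %d (%s)\n",
    x$case_id, nrow(x$img_a), ncol(x$img_a), x$label,
    if (x$label == 1L) "abnormal" else "normal"
  ))
  invisible(x)
}

# A soft-edged blob whose radius is modulated around the boundary; the
# intensity inside carries an oriented sinusoidal texture. All geometry
# parameters are fractions of the image side.
render_archetype <- function(p, size) {
  u <- matrix(seq(0, 1, length.out = size), size, size)        # rows
  v <- matrix(seq(0, 1, length.out = size), size, size, byrow = TRUE)
  du <- u - p$cy
  dv <- v - p$cx
  phi <- atan2(du, dv)
  # elliptical distance in the blob's own frame
  ct <- cos(p$theta); st <- sin(p$theta)
  e1 <- (dv * ct + du * st) / p$rx
  e2 <- (-dv * st + du * ct) / p$ry
  d <- sqrt(e1^2 + e2^2)
  rim <- 1 + p$lobe_amp * sin(p$lobes * phi + p$lobe_phase)
  envelope <- 1 / (1 + exp((d / rim - 1) / p$softness))
  carrier <- sin(2 * pi * p$freq * (v * cos(p$tex_theta) + u * sin(p$tex_theta)) + p$phase)
  field <- envelope * (p$base + p$tex_amp * carrier)
  clip01(field)
}

draw_normal_archetypes <- function(n) {
  lapply(seq_len(n), function(i) {
    list(
      cx = stats::runif(1, 0.45, 0.55), cy = stats::runif(1, 0.45, 0.55),
      rx = stats::runif(1, 0.26, 0.32), ry = stats::runif(1, 0.22, 0.28),
      theta = stats::runif(1, 0, pi),
      lobes = 0, lobe_amp = 0, lobe_phase = 0, softness = 0.08,
      freq = stats::runif(1, 2, 4), tex_theta = stats::runif(1, 0, pi),
      tex_amp = stats::runif(1, 0.05, 0.12), phase = stats::runif(1, 0, 2 * pi),
      base = stats::runif(1, 0.55, 0.7)
    )
  })
}

draw_abnormal_family <- function(n) {
  # each family fixes broad ranges; per-case geometry is drawn at render time
  lapply(seq_len(n), function(i) {
    list(
      freq_lo = stats::runif(1, 3, 9), freq_span = stats::runif(1, 2, 6),
      base_lo = stats::runif(1, 0.3, 0.6), lobe_max = stats::runif(1, 0.25, 0.5)
    )
  })
}

draw_abnormal_case_params <- function(family) {
  list(
    cx = stats::runif(1, 0.3, 0.7), cy = stats::runif(1, 0.3, 0.7),
    rx = stats::runif(1, 0.12, 0.4), ry = stats::runif(1, 0.12, 0.4),
    theta = stats::runif(1, 0, pi),
    lobes = sample(2:8, 1), lobe_amp = stats::runif(1, 0.1, family$lobe_max),
    lobe_phase = stats::runif(1, 0, 2 * pi),
    softness = stats::runif(1, 0.02, 0.12),
    freq = family$freq_lo + stats::runif(1, 0, family$freq_span),
    tex_theta = stats::runif(1, 0, pi),
    tex_amp = stats::runif(1, 0.1, 0.35), phase = stats::runif(1, 0, 2 * pi),
    base = family$base_lo + stats::runif(1, 0, 0.3)
  )
}

# Second-contrast rendering of the same underlying field: gamma-remapped
# intensities with their own noise, emulating the T1/T2 contrast difference.
second_contrast <- function(field, gamma, gain, noise_sd) {
  b <- 0.05 + gain * field^gamma
  clip01(b + matrix(stats::rnorm(length(field), sd = noise_sd), nrow(field)))
}

#' Generate a synthetic imbalanced paired-image cohort
#'
#' Draws `n_normal` cases from a small set of shared archetypes (compact
#' class) and `n_abnormal` cases from archetype families with per-case
#' random geometry (diverse class). Each case carries two correlated
#' renderings of the same underlying field: `img_a` (T1 role) and `img_b`
#' (T2 role, an independent gamma contrast remap with its own noise).
#'
#' @param spec A [cohort_spec()].
#' @return A list of `grayscale_pair_case` objects, normals first; pixel
#'   values in \[0, 1\]. Deterministic given `spec` (including its seed).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_normal = 6, n_abnormal = 2,
#'                                       image_size = 16, seed = 1))
#' length(cohort)
#' cohort_manifest(cohort)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  withr::with_seed(derive_seed(spec$seed, 1L), {
    normal_arch <- draw_normal_archetypes(spec$n_archetypes_normal)
    families <- draw_abnormal_family(spec$n_archetypes_abnormal)
    n_pix <- spec$image_size^2
    make_case <- function(id, label, params) {
      field <- render_archetype(params, spec$image_size)
      jitter <- stats::runif(1, -0.03, 0.03)
      img_a <- clip01(field + jitter +
                        matrix(stats::rnorm(n_pix, sd = spec$noise_sd), spec$image_size))
      img_b <- second_contrast(field, gamma = stats::runif(1, 0.6, 1.6),
                               gain = stats::runif(1, 0.7, 0.9),
                               noise_sd = spec$noise_sd)
      new_grayscale_pair_case(id, img_a, img_b, label)
    }
    normals <- lapply(seq_len(spec$n_normal), function(i) {
      arch <- normal_arch[[1L + (i - 1L) %% spec$n_archetypes_normal]]
      make_case(sprintf("norm%03d", i), 0L, arch)
    })
    abnormals <- lapply(seq_len(spec$n_abnormal), function(i) {
      fam <- families[[1L + (i - 1L) %% spec$n_archetypes_abnormal]]
      make_case(sprintf("abn%03d", i), 1L, draw_abnormal_case_params(fam))
    })
    c(normals, abnormals)
  })
}

#' Tabulate a cohort as a tibble manifest
#'
#' @param cases List of `grayscale_pair_case` objects.
#' @return A tibble with columns `case_id` and `label`.
#' @export
cohort_manifest <- function(cases) {
  tibble::tibble(
    case_id = purrr::map_chr(cases, "case_id"),
    label = purrr::map_int(cases, "label")
  )
}

#' Generate an auxiliary texture library
#'
#' Procedural full-field textures (sinusoidal gratings, plaids,
#' checkerboards, smoothed noise) standing in for a non-medical texture
#' database used as an auxiliary third training class. Each image is
#' min-max normalised to span \[0, 1\].
#'
#' @param n Number of textures.
#' @param size Side length in pixels.
#' @param seed Integer seed.
#' @return A list of `texture_image` objects (fields `image`, `source_id`).
#' @export
generate_texture_library <- function(n = 61, size = 128, seed = 1L) {
  check_number(n, "n", min = 0, integerish = TRUE)
  check_number(size, "size", min = 8, integerish = TRUE)
  withr::with_seed(derive_seed(seed, 2L), {
    u <- matrix(seq(0, 1, length.out = size), size, size)
    v <- t(u)
    lapply(seq_len(n), function(i) {
      kind <- (i - 1L) %% 4L
      img <- switch(as.character(kind),
        "0" = { # grating
          f <- stats::runif(1, 2, 14); th <- stats::runif(1, 0, pi)
          sin(2 * pi * f * (v * cos(th) + u * sin(th)) + stats::runif(1, 0, 2 * pi))
        },
        "1" = { # plaid
          f1 <- stats::runif(1, 2, 10); f2 <- stats::runif(1, 2, 10)
          th <- stats::runif(1, 0, pi)
          sin(2 * pi * f1 * (v * cos(th) + u * sin(th))) +
            sin(2 * pi * f2 * (-v * sin(th) + u * cos(th)))
        },
        "2" = { # checkerboard
          cells <- sample(4:12, 1)
          (floor(u * cells) + floor(v * cells)) %% 2
        },
        "3" = { # box-smoothed white noise
          w <- sample(2:6, 1)
          z <- matrix(stats::rnorm(size^2), size)
          k <- matrix(1 / w^2, w, w)
          sm <- stats::filter(z, rep(1 / w, w), sides = 2, circular = TRUE)
          sm <- t(stats::filter(t(sm), rep(1 / w, w), sides = 2, circular = TRUE))
          matrix(as.numeric(sm), size)
        }
      )
      rng <- range(img)
      if (diff(rng) < .Machine$double.eps) img[] <- 0.5
      else img <- (img - rng[1]) / diff(rng)
      structure(list(image = img, source_id = sprintf("tex%03d", i)),
                class = "texture_image")
    })
  })
}

#' Cross-tabulate cohort composition by label and split
#'
#' Counts cases per class per split, with marginal totals, the bookkeeping
#' usually reported as the "data distribution" table of a study design.
#'
#' @param cases List of `grayscale_pair_case` objects, or a data frame with
#'   columns `case_id` and `label`.
#' @param split_assignment A data frame with columns `case_id` and `split`
#'   (values among `"train"`, `"val"`, `"test"`), or a named character
#'   vector `case_id -> split`. Every case must be assigned exactly once.
#' @return A tibble with one row per class plus a `"total"` row and columns
#'   `class`, `train`, `val`, `test`, `total`.
#' @export
tabulate_composition <- function(cases, split_assignment) {
  manifest <- if (is.data.frame(cases)) tibble::as_tibble(cases) else cohort_manifest(cases)
  if (is.character(split_assignment) && !is.null(names(split_assignment))) {
    split_assignment <- tibble::tibble(
      case_id = names(split_assignment), split = unname(split_assignment)
    )
  }
  split_assignment <- tibble::as_tibble(split_assignment)
  if (anyDuplicated(split_assignment$case_id)) {
    abort_inconsistent("each case must be assigned to exactly one split.")
  }
  missing <- setdiff(manifest$case_id, split_assignment$case_id)
  if (length(missing) > 0) {
    abort_inconsistent(sprintf(
      "unassigned case(s): %s", paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  bad <- setdiff(unique(split_assignment$split), c("train", "val", "test"))
  if (length(bad) > 0) {
    abort_inconsistent(sprintf("unknown split label(s): %s", paste(bad, collapse = ", ")))
  }
  tab <- manifest |>
    dplyr::inner_join(split_assignment, by = "case_id") |>
    dplyr::mutate(class = ifelse(.data$label == 1L, "abnormal", "normal")) |>
    dplyr::count(.data$class, .data$split) |>
    tidyr::pivot_wider(names_from = "split", values_from = "n", values_fill = 0L)
  for (s in c("train", "val", "test")) {
    if (!s %in% names(tab)) tab[[s]] <- 0L
  }
  tab <- tab |>
    dplyr::select("class", "train", "val", "test") |>
    dplyr::arrange(match(.data$class, c("normal", "abnormal"))) |>
    dplyr::mutate(total = .data$train + .data$val + .data$test)
  totals <- tibble::tibble(
    class = "total",
    train = sum(tab$train), val = sum(tab$val), test = sum(tab$test),
    total = sum(tab$total)
  )
  dplyr::bind_rows(tab, totals)
}

#' Reference cohort composition of the emulated study design
#'
#' The per-subtype case counts of the 245-case parotid-tumor cohort that the
#' synthetic generator emulates: 190 benign (normal) and 55 malignant
#' (abnormal) cases distributed over train/validation/test splits of
#' 151/48/46 cases.
#'
#' @return A tibble with columns `subtype`, `class` (`"normal"` /
#'   `"abnormal"`), `train`, `val`, `test`.
#' @export
reference_cohort_counts <- function() {
  tibble::tribble(
    ~subtype,                    ~class,     ~train, ~val, ~test,
    "pleomorphic adenoma",       "normal",       81,   25,    26,
    "Warthin's tumor",           "normal",       18,    6,     5,
    "other benign",              "normal",       17,    7,     5,
    "mucoepidermoid carcinoma",  "abnormal",     13,    3,     3,
    "acinic cell carcinoma",     "abnormal",      5,    2,     1,
    "malignant lymphoma",        "abnormal",      5,    1,     1,
    "other malignant",           "abnormal",     12,    4,     5
  )
}

#' Write a cohort (and optional texture library) to disk
#'
#' Writes one 8-bit grayscale PNG per image (`<case>_a.png`, `<case>_b.png`),
#' a `manifest.csv` (case_id, img_a, img_b, label) and, when textures are
#' given, a `textures/` directory of PNGs.
#'
#' @param cases List of `grayscale_pair_case` objects.
#' @param dir Output directory (created if absent).
#' @param textures Optional list of `texture_image` objects.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cases, dir, textures = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(cases, function(case) {
    fa <- paste0(case$case_id, "_a.png")
    fb <- paste0(case$case_id, "_b.png")
    png::writePNG(case$img_a, file.path(dir, fa))
    png::writePNG(case$img_b, file.path(dir, fb))
    tibble::tibble(case_id = case$case_id, img_a = fa, img_b = fb, label = case$label)
  })
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(textures)) {
    tdir <- file.path(dir, "textures")
    dir.create(tdir, showWarnings = FALSE)
    for (tx in textures) {
      png::writePNG(tx$image, file.path(tdir, paste0(tx$source_id, ".png")))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the PNG pairs.
#' @return A list of `grayscale_pair_case` objects.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  purrr::pmap(manifest, function(case_id, img_a, img_b, label) {
    new_grayscale_pair_case(
      case_id,
      png::readPNG(file.path(dir, img_a)),
      png::readPNG(file.path(dir, img_b)),
      label
    )
  })
}
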