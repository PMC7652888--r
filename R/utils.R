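# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_bad_arg <- function(msg) {
  rlang::abort(msg, class = "deeplof_argument_error")
}

abort_inconsistent <- function(msg) {
  rlang::abort(msg, class = "deeplof_consistency_error")
}

check_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort_bad_arg(sprintf("`%s` must be in [%s, %s].", name, min, max))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort_bad_arg(sprintf("`%s` must be a whole number.", name))
  }
  invisible(x)
}

check_probability <- function(x, name) check_number(x, name, min = 0, max = 1)

# Pixel arrays are H x W (grayscale) or H x W x 3 (color), values in [0, 1].
check_pixels <- function(x, name = "image") {
  if (!is.numeric(x) || !(length(dim(x)) %in% c(2L, 3L) || is.matrix(x))) {
    abort_bad_arg(sprintf("`%s` must be a 2-D matrix or H x W x C array.", name))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort_bad_arg(sprintf("`%s` contains non-finite values.", name))
  }
  invisible(x)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Derive a stream-specific 32-bit seed from a base seed, staying below 2^31.
# Arithmetic in doubles: products up to ~2^42 are exact, integer mult would
# overflow.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483563)
}

is_onehot <- function(w, tol = 1e-8) {
  sum(abs(w - round(w))) < tol && abs(sum(w) - 1) < tol
}
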