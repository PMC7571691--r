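# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Seeds the generator with `seed + offset` (fixed per-generator offsets keep
#' the synthetic-data streams independent of one another), runs `code`, and
#' restores the caller's RNG state afterwards.
#'
#' @param seed integer root seed.
#' @param offset fixed integer offset identifying the generator stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  force(code)
}

# Discrete Fourier transform sample frequencies (cycles per unit), matching
# the usual fft layout: 0, 1/(n*d), ..., then negative frequencies.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

# Stop with a formatted message.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Check a scalar is a finite number within optional bounds.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    abort("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    abort("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower)
    abort("`%s` must be >= %g", name, lower)
  if (x > upper)
    abort("`%s` must be <= %g", name, upper)
  invisible(x)
}
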