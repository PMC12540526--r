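#' Round a percentage half-up to one decimal
#'
#' Frequency tables in the turtle literature report percentages rounded
#' half-up (so 1.35 -> 1.4), not with banker's rounding. Used wherever the
#' package prints percentage frequencies.
#'
#' @param x numeric vector of percentages.
#' @return `x` rounded half-up to one decimal place.
#' @export
percent_round1 <- function(x) {
  # add a hair of slack so values like 74.35 stored as 74.34999... round up
  floor(x * 10 + 0.5 + 1e-9) / 10
}

#' Derive a subsidiary seed from a master seed
#'
#' One master seed fans out to per-component seeds via a fixed affine
#' counter scheme, so partial pipeline reruns are reproducible without
#' sharing RNG state between stages. Results stay below 2^31.
#'
#' @param seed master integer seed.
#' @param index nonnegative integer counter identifying the component.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  as.integer((as.double(seed) + 1009 * as.double(index)) %% 2147483647)
}

# internal: stop with a consistent message prefix
ts_stop <- function(...) stop(..., call. = FALSE)

ts_warn <- function(...) warning(..., call. = FALSE)

# internal: check a scalar probability-like value
check_prob <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) ts_stop(sprintf("'%s' must be a single value in %s", name,
                           if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}
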