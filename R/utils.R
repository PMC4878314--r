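# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic rounding used everywhere a count or percentage is rounded,
#' so that outputs are bit-comparable across platforms (base `round()` uses
#' banker's rounding).
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5))   # 1, 2, -1
#' round_half_away(31.85, 1)            # 31.9
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL means "use the current stream".
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
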