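#' Round half up to a fixed number of decimals
#'
#' Rounds positive values with ties going up (0.05 -> 0.1 at one decimal),
#' the convention used for the percentage tables produced by
#' [summarize_annotation()]. Base `round()` rounds half to even, which is
#' unsuitable for reproducing printed percentages.
#'
#' @param x numeric vector (non-negative in the intended use).
#' @param digits number of decimal places.
#' @return numeric vector rounded half up.
#' @examples
#' round_half_up(100 * 180 / 1539, 1)  # 11.7
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

# round half away from zero to an integer (normalized counts, allocations)
.round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

.assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (x < min) {
    stop(sprintf("'%s' must be >= %s", name, format(min)), call. = FALSE)
  }
  invisible(x)
}

# sign as {-1, 0, 1} integer
.sign_int <- function(x) as.integer(sign(x))

.dir_symbol <- function(s) c("-", "0", "+")[s + 2L]

.dir_sign <- function(sym) {
  out <- integer(length(sym))
  out[sym == "+"] <- 1L
  out[sym == "-"] <- -1L
  out
}
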