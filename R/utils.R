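#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the previous RNG state so that
#' seeded package functions never disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Commercial rounding (0.005 -> 0.01, -0.005 -> -0.01), used when comparing
#' recomputed log2 fold changes against published tables, which use this
#' convention rather than R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.165, -0.165, 0.044), 2)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  out <- sign(x) * floor(abs(x) * p + 0.5) / p
  out[!is.finite(x)] <- x[!is.finite(x)]
  out
}

# derive a per-stream seed from a master seed; stays well below 2^31
stream_seed <- function(seed, stream) {
  (as.integer(seed) %% 2000000L) * 1000L + as.integer(stream)
}
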