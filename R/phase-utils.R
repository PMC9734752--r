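#' Wrap angles to (-pi, pi]
#'
#' @param theta Numeric vector of angles in radians.
#' @return Angles wrapped to the half-open interval (-pi, pi].
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_phase <- function(theta) {
  w <- theta %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Unwrap a phase series
#'
#' Nearest-branch unwrapping: successive differences are wrapped to
#' (-pi, pi] and re-accumulated, removing the 2*pi jumps of a wrapped series.
#'
#' @param theta Numeric vector of (possibly wrapped) phases in radians.
#' @return Continuous phase series starting at `theta[1]`.
#' @export
unwrap_phase <- function(theta) {
  if (length(theta) < 2L) return(theta)
  theta[1] + c(0, cumsum(wrap_phase(diff(theta))))
}

# deterministic 31-bit stream-seed derivation; keeps all intermediates
# below 2^53 so the arithmetic is exact in doubles on every platform
derive_seed <- function(seed, stream) {
  s <- (abs(as.numeric(seed)) %% 65521) + 1
  k <- abs(as.numeric(stream)) %% 65521
  x <- (s * 40503 + k * 30011 + 12345) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x)
}
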