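#' Classic one-dimensional gradient (Perlin) noise
#'
#' Continuous, band-limited noise used to modulate the circle radius of the
#' virtual hands. Gradients of +/-1 are assigned to the integer lattice
#' (one node per second) by a deterministic integer hash of `(node, seed)`,
#' and values between nodes are blended with the quintic fade
#' `6 f^5 - 15 f^4 + 10 f^3`. The raw noise has theoretical extremes of
#' +/-1/2 (attained at mid-lattice when adjacent gradients oppose), so the
#' output is rescaled by `2 * amplitude` to span exactly
#' `[-amplitude, amplitude]`. The noise vanishes at every lattice node.
#'
#' The function is total and fully deterministic in `(t, seed)`; it never
#' touches R's global RNG state. All hash arithmetic stays below 2^53 so
#' results are bit-identical across platforms.
#'
#' @param t Time in seconds (vectorised), `t >= 0`.
#' @param seed Integer stream seed; different seeds give independent streams.
#' @param amplitude Half-range in metres, `>= 0` (default `0.085`).
#'
#' @return Numeric vector of noise values in `[-amplitude, amplitude]`.
#' @examples
#' perlin_noise(0:10, seed = 1)          # zero at every lattice node
#' max(abs(perlin_noise(seq(0, 60, by = 0.001), seed = 7))) # <= 0.085
#' @export
perlin_noise <- function(t, seed, amplitude = 0.085) {
  stopifnot(is.numeric(t), all(is.finite(t)),
            is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0)
  if (amplitude == 0) return(numeric(length(t)))
  n0 <- floor(t)
  f <- t - n0
  g0 <- perlin_gradient(n0, seed)
  g1 <- perlin_gradient(n0 + 1, seed)
  u <- f * f * f * (f * (f * 6 - 15) + 10)
  v <- (1 - u) * (g0 * f) + u * (g1 * (f - 1))
  2 * amplitude * v
}

# +/-1 gradient at integer lattice nodes: two rounds of a multiplicative
# congruential mix modulo the Mersenne prime 2^31 - 1, thresholded at the
# midpoint. Exact in double precision (all products < 2^53).
perlin_gradient <- function(node, seed) {
  s <- (abs(as.numeric(seed)) %% 65521) + 1
  m <- as.numeric(node) %% 65521
  x <- (m * 40503 + s * 30011 + 12345) %% 2147483647
  x <- (x * 48271) %% 2147483647
  x <- (x * 69621) %% 2147483647
  ifelse(x + x < 2147483647, 1, -1)
}
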