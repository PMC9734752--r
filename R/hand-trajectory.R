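#' Timestamped 3-D trajectory of one hand
#'
#' The common currency of the simulator and the analysis functions: a uniform
#' time grid and one 3-D position (metres) per sample. Coordinates follow the
#' package frame: x along the facing axis (normal of the movement plane),
#' y vertical, z lateral.
#'
#' @param side `"right"` or `"left"`.
#' @param times Numeric vector of sample times in seconds; strictly
#'   increasing and uniformly spaced (tolerance 1e-9 s).
#' @param positions Numeric matrix with one row per sample and columns
#'   `x, y, z`, in metres; all values finite.
#'
#' @return An object of class `hand_trajectory`.
#' @export
hand_trajectory <- function(side = c("right", "left"), times, positions) {
  side <- match.arg(side)
  times <- as.numeric(times)
  positions <- as.matrix(positions)
  if (length(times) == 0L) stop("empty trajectory: no samples", call. = FALSE)
  if (!is.numeric(positions) || ncol(positions) != 3L)
    stop("positions must be a numeric matrix with 3 columns (x, y, z)",
         call. = FALSE)
  if (nrow(positions) != length(times))
    stop("positions and times must have the same number of samples",
         call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(positions)))
    stop("trajectory contains non-finite values", call. = FALSE)
  if (length(times) > 1L) {
    dts <- diff(times)
    if (any(dts <= 0)) {
      bad <- times[which(dts <= 0)[1] + 1L]
      stop(sprintf("times must be strictly increasing (first offending timestamp: %.6f s)",
                   bad), call. = FALSE)
    }
    if (max(dts) - min(dts) > 1e-9)
      stop("non-uniform time grid: sample spacing varies by more than 1e-9 s",
           call. = FALSE)
  }
  colnames(positions) <- c("x", "y", "z")
  structure(list(side = side, times = times, positions = positions),
            class = "hand_trajectory")
}

#' @export
print.hand_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<hand_trajectory %s> %d samples over %.2f s\n",
              x$side, n, x$times[n] - x$times[1]))
  invisible(x)
}

#' @export
length.hand_trajectory <- function(x) length(x$times)

#' Sample rate of a trajectory
#' @param traj A [hand_trajectory()].
#' @return Samples per second (Hz).
#' @export
trajectory_rate <- function(traj) {
  if (length(traj$times) < 2L)
    stop("cannot infer sample rate from fewer than 2 samples", call. = FALSE)
  1 / mean(diff(traj$times))
}
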