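#' Instantaneous phase of a hand trajectory
#'
#' Inverts the circular kinematics: with the circle centre `c`, the right
#' hand's phase is `atan2(y - c_y, z - c_z)` and the left hand's
#' `atan2(y - c_y, -(z - c_z))` (the left hand counter-rotates laterally).
#' The centre defaults to the trajectory's mean position. Samples closer
#' than `r_min` to the centre carry no usable angle and repeat the previous
#' phase (freeze rule); a trajectory with fewer than 10% usable samples is
#' rejected as degenerate.
#'
#' This centred-arctangent estimator matches the generative circle model
#' exactly and is causal; a Hilbert-transform alternative is deliberately
#' not used (see the package vignette).
#'
#' @param trajectory A [hand_trajectory()].
#' @param center Optional 3-vector overriding the circle centre (metres).
#' @param r_min Freeze radius in metres (default 0.03).
#' @param source `"human"` or `"virtual"`, recorded on the result.
#' @return An object of class `phase_series`: list with `times`, wrapped
#'   `phases`, `side` and `source`.
#' @export
extract_phase <- function(trajectory, center = NULL, r_min = 0.03,
                          source = c("human", "virtual")) {
  source <- match.arg(source)
  stopifnot(inherits(trajectory, "hand_trajectory"))
  if (is.null(center)) center <- colMeans(trajectory$positions)
  rel <- sweep(trajectory$positions, 2, center)
  d <- sqrt(rel[, 2]^2 + rel[, 3]^2)
  usable <- d >= r_min
  if (mean(usable) < 0.1)
    stop("degenerate trajectory: fewer than 10% of samples move beyond r_min",
         call. = FALSE)
  zsign <- if (trajectory$side == "right") 1 else -1
  theta <- atan2(rel[, 2], zsign * rel[, 3])
  if (any(!usable)) {
    # freeze rule: carry the last usable phase forward
    idx <- which(usable)
    carry <- findInterval(seq_along(theta), idx)
    frozen <- carry >= 1L
    theta[!usable & frozen] <- theta[idx][carry[!usable & frozen]]
  }
  structure(
    list(times = trajectory$times, phases = wrap_phase(theta),
         side = trajectory$side, source = source),
    class = "phase_series"
  )
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series %s/%s> %d samples\n",
              x$source, x$side, length(x$times)))
  invisible(x)
}

#' Relative phase between two phase series
#'
#' @param a,b [extract_phase()] results (or lists with `times` and `phases`)
#'   on identical time grids.
#' @return Numeric series of wrapped phase differences `a - b` in rad.
#' @export
relative_phase <- function(a, b) {
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9)
    stop("phase series are not on the same time grid", call. = FALSE)
  wrap_phase(a$phases - b$phases)
}

#' Kuramoto order parameter
#'
#' Magnitude of the mean unit phasor across streams at each instant:
#' `R(t) = |mean_j exp(i theta_j(t))|`. 1 means all streams share a phase,
#' values near 0 mean incoherence.
#'
#' @param phases Numeric matrix with one column per phase stream (at least
#'   2), or a list of equal-length phase vectors.
#' @return Numeric series in `[0, 1]`, one value per row/instant.
#' @export
order_parameter <- function(phases) {
  if (is.list(phases) && !is.matrix(phases))
    phases <- do.call(cbind, lapply(phases, function(p)
      if (inherits(p, "phase_series")) p$phases else p))
  phases <- as.matrix(phases)
  if (ncol(phases) < 2L)
    stop("order parameter needs at least 2 phase streams", call. = FALSE)
  Mod(rowMeans(exp(1i * phases)))
}

#' Detect phase-locked intervals
#'
#' Flags spans where the windowed mean absolute derivative of the unwrapped
#' relative phase stays below `tolerance`. The rolling mean uses a centred
#' window (shortened at the edges so a fully locked series yields one
#' interval covering the whole trial); adjacent locked runs are merged by
#' construction.
#'
#' @param rel_phase Relative-phase series in rad (wrapped or not).
#' @param sample_rate Hz.
#' @param window Averaging window in seconds, `>= 1`.
#' @param tolerance Maximum mean absolute phase drift rate, rad/s.
#' @return Data frame with columns `start`, `end` (seconds), one row per
#'   locked interval; zero rows if never locked.
#' @export
detect_lock <- function(rel_phase, sample_rate, window = 2, tolerance = 0.1) {
  stopifnot(window >= 1, sample_rate > 0, tolerance > 0)
  n <- length(rel_phase)
  if (n < 2L) return(data.frame(start = numeric(0), end = numeric(0)))
  uw <- unwrap_phase(wrap_phase(rel_phase))
  speed <- abs(diff(uw)) * sample_rate          # between-sample drift speeds
  half <- max(1L, as.integer(round(window * sample_rate / 2)))
  cs <- cumsum(c(0, speed))
  m <- length(speed)
  lo <- pmax(1L, seq_len(m) - half)
  hi <- pmin(m, seq_len(m) + half)
  rolled <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  locked <- c(rolled[1], rolled) < tolerance    # per-sample flag
  r <- rle(locked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  times <- (seq_len(n) - 1L) / sample_rate
  data.frame(start = times[starts[keep]], end = times[ends[keep]])
}

#' Fraction of a trial covered by detected lock intervals
#'
#' @inheritParams detect_lock
#' @param from Ignore everything before this time (seconds), e.g. to drop a
#'   transient.
#' @return Fraction in `[0, 1]` of the analysed span that is locked.
#' @export
lock_fraction <- function(rel_phase, sample_rate, window = 2, tolerance = 0.1,
                          from = 0) {
  n <- length(rel_phase)
  span <- (n - 1L) / sample_rate
  iv <- detect_lock(rel_phase, sample_rate, window, tolerance)
  if (nrow(iv) == 0L || span <= from) return(0)
  covered <- sum(pmax(0, pmin(iv$end, span) - pmax(iv$start, from)))
  covered / (span - from)
}

#' Time-in-sync summary of a button stream
#'
#' @param button Logical (or 0/1) series of button states at `sample_rate`.
#' @param sample_rate Hz.
#' @param condition Optional condition label carried on the report.
#' @return An object of class `sync_report`: `time_pressed` (seconds),
#'   `ratio` (fraction of samples pressed), `duration` (series span in
#'   seconds) and `condition`.
#' @export
sync_time <- function(button, sample_rate, condition = NA_character_) {
  stopifnot(length(button) > 0, sample_rate > 0)
  button <- as.logical(button)
  stopifnot(!anyNA(button))
  structure(
    list(condition = condition,
         time_pressed = sum(button) / sample_rate,
         ratio = mean(button),
         duration = length(button) / sample_rate),
    class = "sync_report"
  )
}

#' @export
print.sync_report <- function(x, ...) {
  cat(sprintf("<sync_report%s> %.2f s pressed of %.2f s (ratio %.3f)\n",
              if (is.na(x$condition)) "" else paste0(" ", x$condition),
              x$time_pressed, x$duration, x$ratio))
  invisible(x)
}

#' Per-trial synchrony metrics
#'
#' Convenience wrapper computing, from a [run_trial()] record, the mean
#' order parameter of the facing hand pair (human right vs virtual left),
#' the locked fraction of the trial, and the button-derived time in sync.
#'
#' @param trial A `trial_record`.
#' @param window,tolerance Passed to [lock_fraction()].
#' @return One-row data frame: `condition`, `mean_R`, `lock_fraction`,
#'   `time_pressed_s`, `ratio`.
#' @export
trial_metrics <- function(trial, window = 2, tolerance = 0.25) {
  ph <- extract_phase(trial$human_right, source = "human")
  pv <- extract_phase(trial$virtual_left, source = "virtual")
  rel <- relative_phase(ph, pv)
  fs <- trial$config$sample_rate
  rep <- sync_time(trial$button, fs, trial$condition)
  data.frame(
    condition = trial$condition,
    mean_R = mean(order_parameter(cbind(ph$phases, pv$phases))),
    lock_fraction = lock_fraction(rel, fs, window, tolerance),
    time_pressed_s = rep$time_pressed,
    ratio = rep$ratio
  )
}
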