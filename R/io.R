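#' Write hand trajectories to CSV
#'
#' One file per player per trial, header `t,side,x,y,z`: time in seconds and
#' coordinates in metres, both serialised with 6 decimals (angles elsewhere
#' in the package are radians, lengths metres).
#'
#' @param traj A [hand_trajectory()], or a list of them (e.g. `right` and
#'   `left` of one player).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (inherits(traj, "hand_trajectory")) traj <- list(traj)
  rows <- lapply(traj, function(tr) {
    stopifnot(inherits(tr, "hand_trajectory"))
    data.frame(t = sprintf("%.6f", tr$times),
               side = tr$side,
               x = sprintf("%.6f", tr$positions[, 1]),
               y = sprintf("%.6f", tr$positions[, 2]),
               z = sprintf("%.6f", tr$positions[, 3]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a hand trajectory from CSV
#'
#' Reads the `t,side,x,y,z` format written by [write_trajectory()]. A file
#' may hold one side or both; when both are present, `side` selects which
#' one to return (or use [read_player()] for both). Non-monotone or
#' non-uniform time grids are rejected with the first offending timestamp.
#'
#' @param path CSV path.
#' @param side `NULL` (file must contain a single side) or `"right"`/
#'   `"left"`.
#' @return A [hand_trajectory()].
#' @export
read_trajectory <- function(path, side = NULL) {
  df <- read_trajectory_table(path)
  sides <- unique(df$side)
  if (is.null(side)) {
    if (length(sides) > 1L)
      stop(sprintf("%s contains both sides; pass side = \"right\" or \"left\"",
                   path), call. = FALSE)
    side <- sides
  }
  if (!side %in% sides)
    stop(sprintf("%s: no rows for side '%s'", path, side), call. = FALSE)
  sub <- df[df$side == side, ]
  hand_trajectory(side, sub$t, as.matrix(sub[, c("x", "y", "z")]))
}

#' Read both hands of one player from a trajectory CSV
#' @param path CSV path containing rows for both sides.
#' @return List with [hand_trajectory()] elements `right` and `left`.
#' @export
read_player <- function(path) {
  list(right = read_trajectory(path, "right"),
       left = read_trajectory(path, "left"))
}

read_trajectory_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (file.size(path) == 0L)
    stop(sprintf("empty input file: %s", path), call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(trimws(header), c("t", "side", "x", "y", "z")))
    stop(sprintf("%s: malformed header (expected 't,side,x,y,z', got '%s')",
                 path, paste(header, collapse = ",")), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop(sprintf("empty input file (header only): %s", path), call. = FALSE)
  if (!all(df$side %in% c("right", "left")))
    stop(sprintf("%s: column 'side' must be 'right' or 'left'", path),
         call. = FALSE)
  df
}

#' Write / read a button-press stream
#'
#' CSV with header `t,pressed`, `pressed` serialised as 0/1.
#'
#' @param button Logical series.
#' @param sample_rate Hz (times are `0, 1/rate, ...`).
#' @param path CSV path.
#' @return `write_button`: `path` invisibly; `read_button`: list with
#'   numeric `t` and logical `pressed`.
#' @export
write_button <- function(button, sample_rate, path) {
  t <- (seq_along(button) - 1L) / sample_rate
  utils::write.csv(data.frame(t = sprintf("%.6f", t),
                              pressed = as.integer(button)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_button
#' @export
read_button <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), c("t", "pressed")))
    stop(sprintf("%s: malformed header (expected 't,pressed')", path),
         call. = FALSE)
  if (!all(df$pressed %in% c(0L, 1L)))
    stop(sprintf("%s: column 'pressed' must be 0/1", path), call. = FALSE)
  list(t = df$t, pressed = as.logical(df$pressed))
}

#' Read / write the questionnaire CSV
#'
#' Format: `participant,condition,question,response` with responses as
#' integers in `[-3, 3]`.
#'
#' @param table Questionnaire data frame (see [generate_questionnaire()]).
#' @param path CSV path.
#' @export
write_questionnaire <- function(table, path) {
  utils::write.csv(table[, c("participant", "condition", "question",
                             "response")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_questionnaire
#' @export
read_questionnaire <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant", "condition", "question", "response")
  if (!all(needed %in% names(df)))
    stop(sprintf("%s: expected columns %s", path,
                 paste(needed, collapse = ",")), call. = FALSE)
  if (any(df$response < -3 | df$response > 3))
    stop(sprintf("%s: column 'response' out of the -3..3 scale", path),
         call. = FALSE)
  df
}

#' Read / write the per-participant sync-times CSV
#'
#' Format: `participant,condition,time_pressed_s` (seconds).
#'
#' @param sync_times Data frame with those columns.
#' @param path CSV path.
#' @export
write_sync_times <- function(sync_times, path) {
  utils::write.csv(sync_times[, c("participant", "condition",
                                  "time_pressed_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sync_times
#' @export
read_sync_times <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant", "condition", "time_pressed_s")
  if (!all(needed %in% names(df)))
    stop(sprintf("%s: expected columns %s", path,
                 paste(needed, collapse = ",")), call. = FALSE)
  df
}

#' Read / write a flat key-value configuration file
#'
#' Lines of the form `key = value`; recognised keys are the fields of
#' [model_config()] plus `seed`. Unknown keys are rejected.
#'
#' @param path Config file path.
#' @return `read_config`: list with a `config` ([model_config()]) and a
#'   `seed` (or `NULL`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop(sprintf("%s: each line must be 'key = value'", path), call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  allowed <- c("k_inter", "k_intra", "noise_amplitude", "sample_rate",
               "plane_offset", "partner_distance", "duration", "seed")
  if (any(!keys %in% allowed))
    stop(sprintf("%s: unknown key(s): %s", path,
                 paste(setdiff(keys, allowed), collapse = ", ")),
         call. = FALSE)
  if (anyNA(vals))
    stop(sprintf("%s: non-numeric value", path), call. = FALSE)
  named <- as.list(vals)
  names(named) <- keys
  seed <- named$seed
  named$seed <- NULL
  list(config = do.call(model_config, named),
       seed = if (is.null(seed)) NULL else as.integer(seed))
}

#' @rdname read_config
#' @param config A [model_config()].
#' @param seed Optional integer seed to record.
#' @export
write_config <- function(config, path, seed = NULL) {
  keys <- c("k_inter", "k_intra", "noise_amplitude", "sample_rate",
            "plane_offset", "partner_distance", "duration")
  lines <- sprintf("%s = %.10g", keys,
                   vapply(keys, function(k) config[[k]], 1))
  if (!is.null(seed)) lines <- c(lines, sprintf("seed = %d", as.integer(seed)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Every CLI run emits one JSON manifest recording the command, the full
#' configuration snapshot, the seed, input/output paths, the package
#' version and a timestamp — enough to reproduce the run's outputs.
#'
#' @param path Output JSON path.
#' @param command CLI subcommand name.
#' @param config A [model_config()] (or `NULL`).
#' @param seed Integer seed.
#' @param inputs,outputs Character vectors of file paths.
#' @param extra Named list of additional fields to record.
#' @export
write_manifest <- function(path, command, config = NULL, seed = NA_integer_,
                           inputs = character(0), outputs = character(0),
                           extra = list()) {
  manifest <- c(list(
    command = command,
    config = if (is.null(config)) NULL else unclass(config),
    seed = as.integer(seed),
    inputs = as.character(inputs),
    outputs = as.character(outputs),
    tool_version = as.character(utils::packageVersion("mirrorplayer")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
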