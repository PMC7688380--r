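# Device-calibration numerics: dB HL <-> dB SPL via a RETSPL table, the
# ascending 1-dB threshold search, the 2-down/1-up staircase, and
# channel/device output-difference checks.
#
# The 2-down/1-up rule converges on the level where the response
# probability equals 1/sqrt(2) ~ 0.707 (two consecutive responses are then
# as likely as a descent demands), the classic transformed up-down target.

#' Reference-equivalent threshold SPL table
#'
#' Maps frequency to the dB SPL offset corresponding to 0 dB HL for a given
#' transducer.  The default is an identity table (all offsets 0) for pure
#' simulation; real transducer values can be supplied per frequency.
#'
#' @param freq_hz frequencies covered, Hz.
#' @param offset_db RETSPL offsets in dB, recycled to length of `freq_hz`.
#' @return data frame of class `retspl` with columns `freq_hz`, `offset_db`.
#' @export
retspl_table <- function(freq_hz = CALIBRATION_FREQUENCIES, offset_db = 0) {
  offset_db <- rep_len(as.numeric(offset_db), length(freq_hz))
  if (any(!is.finite(offset_db))) stop("RETSPL offsets must be finite")
  structure(data.frame(freq_hz = as.integer(freq_hz), offset_db = offset_db),
            class = c("retspl", "data.frame"))
}

.retspl_offset <- function(table, freq) {
  i <- match(as.integer(freq), table$freq_hz)
  if (anyNA(i)) {
    stop("frequency ", paste(freq[is.na(i)], collapse = ", "),
         " Hz not in RETSPL table")
  }
  table$offset_db[i]
}

#' Convert between dB HL and dB SPL
#'
#' `dbhl_to_dbspl()` adds the transducer's RETSPL offset at the given
#' frequency; `dbspl_to_dbhl()` subtracts it.  The two are exact inverses.
#'
#' @param level level in dB HL (or dB SPL for the inverse).
#' @param freq frequency, Hz.
#' @param table a [retspl_table].
#' @return numeric level.
#' @export
dbhl_to_dbspl <- function(level, freq, table = retspl_table()) {
  level + .retspl_offset(table, freq)
}

#' @rdname dbhl_to_dbspl
#' @export
dbspl_to_dbhl <- function(level, freq, table = retspl_table()) {
  level - .retspl_offset(table, freq)
}

#' Ascending threshold search with a fixed step
#'
#' Increments the level from `start` in steps of `step` dB until the first
#' response; returns that level.  A response at the starting level is
#' degenerate (the start was not below the threshold region) and is
#' returned with a warning.
#'
#' @param responder function of one argument (level) returning logical; see
#'   [listener_responder()] to adapt a [listener].
#' @param start starting level, dB.
#' @param step step size, dB (default 1).
#' @param max_level search ceiling; exceeding it without a response is an
#'   error.
#' @return first responding level, dB.
#' @export
ascending_threshold <- function(responder, start, step = 1, max_level = 120) {
  stopifnot(is.function(responder), step > 0)
  level <- start
  first <- TRUE
  while (level <= max_level) {
    if (responder(level)) {
      if (first) warning("response at the starting level; start was not ",
                         "below the threshold region")
      return(level)
    }
    first <- FALSE
    level <- level + step
  }
  stop("no response up to ", max_level, " dB")
}

#' Adapt a listener into a single-frequency responder function
#'
#' @param l a [listener].
#' @param freq frequency, Hz.
#' @param ear `"left"` or `"right"`.
#' @return function(level) -> logical, drawing from the listener's private
#'   random stream.
#' @export
listener_responder <- function(l, freq, ear) {
  stopifnot(inherits(l, "listener"))
  ear <- match.arg(ear, c("left", "right"))
  threshold_at(l$audiogram, ear, freq)
  function(level) respond(l, level, freq, ear)
}

#' Configuration of the 2-down/1-up calibration staircase
#'
#' @param step_db step size, dB (default 1).
#' @param stop_reversals reversals after which the run stops (default 3,
#'   the calibration protocol).
#' @param start_offset_db starting level relative to the known threshold
#'   (default -10 dB).
#' @param discard_reversals initial reversals excluded from the estimate
#'   (default 0; set > 0 with a larger `stop_reversals` to read the
#'   staircase's asymptote).
#' @param max_trials safety cap.
#' @return a list of class `staircase_config`.
#' @export
staircase_config <- function(step_db = 1, stop_reversals = 3L,
                             start_offset_db = -10, discard_reversals = 0L,
                             max_trials = 1000L) {
  stopifnot(step_db > 0, stop_reversals >= 1L,
            discard_reversals >= 0L, discard_reversals < stop_reversals)
  structure(list(step_db = step_db, stop_reversals = as.integer(stop_reversals),
                 start_offset_db = start_offset_db,
                 discard_reversals = as.integer(discard_reversals),
                 max_trials = as.integer(max_trials)),
            class = "staircase_config")
}

#' 2-down/1-up adaptive staircase
#'
#' Starts `start_offset_db` below the known threshold.  Two consecutive
#' responses move the level down one step; any non-response moves it up one
#' step.  A reversal is a change of movement direction; the run stops after
#' `stop_reversals` reversals and the threshold estimate is the mean of the
#' (retained) reversal levels.  The rule converges on the 70.7% point of
#' the psychometric function.
#'
#' @param responder function(level) -> logical.
#' @param known_threshold previously determined threshold the start offset
#'   is taken from, dB.
#' @param config a [staircase_config].
#' @param level_bounds hard bounds; running past them is an error.
#' @return list with `estimate` (dB), `reversals` (levels), `n_trials`.
#' @export
staircase_2down1up <- function(responder, known_threshold,
                               config = staircase_config(),
                               level_bounds = c(-60, 140)) {
  stopifnot(is.function(responder))
  level <- known_threshold + config$start_offset_db
  consec <- 0L
  prev_dir <- 0L
  reversals <- numeric(0)
  n <- 0L
  while (length(reversals) < config$stop_reversals) {
    if (n >= config$max_trials) stop("staircase did not stop within ",
                                     config$max_trials, " trials")
    if (level < level_bounds[1] || level > level_bounds[2]) {
      stop("staircase ran beyond level bounds at ", level, " dB")
    }
    r <- responder(level)
    n <- n + 1L
    if (r) {
      consec <- consec + 1L
      move <- if (consec == 2L) { consec <- 0L; -1L } else 0L
    } else {
      consec <- 0L
      move <- 1L
    }
    if (move != 0L) {
      if (prev_dir != 0L && move != prev_dir) reversals <- c(reversals, level)
      prev_dir <- move
      level <- level + move * config$step_db
    }
  }
  keep <- reversals[(config$discard_reversals + 1L):length(reversals)]
  list(estimate = mean(keep), reversals = reversals, n_trials = n)
}

#' Output-difference check between two transducer channels or devices
#'
#' Compares per-frequency output tables (dB SPL) and passes if the maximum
#' absolute difference is strictly below the limit: 1 dB for left/right
#' EarPod channels, 1.5 dB for device-to-device comparisons.
#'
#' @param a,b named numeric vectors (names = frequency in Hz) or
#'   data frames with columns `freq_hz`, `value_db`.
#' @param limit_db pass limit in dB (default 1).
#' @return list with `max_diff_db`, `pass`, and the per-frequency `diff_db`.
#' @export
channel_balance_check <- function(a, b, limit_db = 1) {
  as_tab <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$value_db, x$freq_hz) else x
  }
  a <- as_tab(a); b <- as_tab(b)
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b))) {
    stop("the two output tables must cover the same frequency set")
  }
  b <- b[names(a)]
  d <- abs(a - b)
  list(max_diff_db = max(d), pass = max(d) < limit_db, diff_db = d)
}
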