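# Conventional pure-tone audiometry: modified Hughson-Westlake threshold
# search, 1 kHz retest reliability, PTA and Siegel grading.

#' Configuration of the modified Hughson-Westlake procedure
#'
#' Textbook defaults: start at 30 dB HL, descend 10 dB after each response,
#' ascend 5 dB after each non-response; threshold is the lowest level with
#' at least 2 responses out of up to 3 ascending presentations.
#'
#' @param start_level first presentation level, dB HL.
#' @param down_step,up_step staircase steps in dB (positive).
#' @param level_bounds audiometer output range, dB HL.
#' @param ascending_criterion responses required at a level, out of
#'   `ascending_max` ascending presentations.
#' @param ascending_max ascending presentations allowed per level before the
#'   level is ruled out.
#' @param max_presentations safety cap per frequency.
#' @param freq_order testing order; 1 kHz is retested last for the
#'   reliability check.
#' @return a list of class `hw_config`.
#' @export
hw_config <- function(start_level = 30, down_step = 10, up_step = 5,
                      level_bounds = c(-10, 120),
                      ascending_criterion = 2L, ascending_max = 3L,
                      max_presentations = 200L,
                      freq_order = c(1000L, 2000L, 4000L, 500L)) {
  stopifnot(down_step > 0, up_step > 0, level_bounds[1] < level_bounds[2],
            ascending_criterion >= 1L,
            ascending_max >= ascending_criterion)
  structure(list(start_level = start_level, down_step = down_step,
                 up_step = up_step, level_bounds = level_bounds,
                 ascending_criterion = as.integer(ascending_criterion),
                 ascending_max = as.integer(ascending_max),
                 max_presentations = as.integer(max_presentations),
                 freq_order = as.integer(freq_order)),
            class = "hw_config")
}

#' Modified Hughson-Westlake threshold for one frequency
#'
#' Descend `down_step` after each response, ascend `up_step` after each
#' non-response; the threshold is the lowest level collecting the ascending
#' criterion (2 of up to 3 ascending responses).  A listener who never meets
#' the criterion up to the audiometer ceiling is returned the ceiling level
#' with `ceiling = TRUE`; responses at the floor count toward the criterion
#' (nothing quieter can be presented).
#'
#' @param l a [listener].
#' @param freq test frequency, Hz.
#' @param ear `"left"` or `"right"`.
#' @param config an [hw_config].
#' @return list with `threshold` (dB HL), `ceiling`, `floor`, and
#'   `n_presentations`.
#' @examples
#' ag <- audiogram(left = c(42, 42, 42, 42), right = c(42, 42, 42, 42))
#' hughson_westlake_threshold(listener(ag, deterministic = TRUE),
#'                            1000, "right")$threshold  # 45
#' @export
hughson_westlake_threshold <- function(l, freq, ear, config = hw_config()) {
  stopifnot(inherits(l, "listener"))
  ear <- match.arg(ear, c("left", "right"))
  threshold_at(l$audiogram, ear, freq)
  ask <- .responder_for(l, ear)
  old <- if (!l$deterministic) .listener_rng_begin(l) else NULL
  if (!l$deterministic) on.exit(.listener_rng_end(l, old))

  lo <- config$level_bounds[1]; hi <- config$level_bounds[2]
  asc_resp <- new.env(parent = emptyenv())  # level -> ascending responses
  asc_vis <- new.env(parent = emptyenv())   # level -> ascending visits
  bump <- function(e, key) {
    cur <- if (is.null(e[[key]])) 0L else e[[key]]
    e[[key]] <- cur + 1L
    e[[key]]
  }

  level <- min(max(config$start_level, lo), hi)
  arrived_up <- FALSE
  n <- 0L
  ceiling_visits <- 0L
  repeat {
    if (n >= config$max_presentations) {
      return(list(threshold = NA_real_, ceiling = FALSE, floor = FALSE,
                  n_presentations = n))
    }
    r <- ask(level, freq)
    n <- n + 1L
    key <- as.character(level)
    counts_ascending <- arrived_up || (r && level <= lo)
    if (counts_ascending) {
      vis <- bump(asc_vis, key)
      if (r) {
        if (bump(asc_resp, key) >= config$ascending_criterion) {
          return(list(threshold = level, ceiling = FALSE,
                      floor = level <= lo, n_presentations = n))
        }
      }
      if (vis >= config$ascending_max) {
        # criterion missed within the window: start a fresh block of visits
        asc_vis[[key]] <- 0L
        asc_resp[[key]] <- 0L
      }
      if (!r && level >= hi) {
        ceiling_visits <- ceiling_visits + 1L
        if (ceiling_visits >= config$ascending_max) {
          return(list(threshold = hi, ceiling = TRUE, floor = FALSE,
                      n_presentations = n))
        }
      }
    }
    if (r) {
      nxt <- max(level - config$down_step, lo)
      arrived_up <- FALSE
    } else {
      nxt <- min(level + config$up_step, hi)
      arrived_up <- nxt > level || level >= hi
    }
    level <- nxt
  }
}

#' Run the full pure-tone exam on a listener
#'
#' Measures air-conduction thresholds at 1, 2, 4 and 0.5 kHz per ear with
#' the modified Hughson-Westlake procedure; 1 kHz is tested twice per ear
#' and the ear is flagged unreliable if the two measures differ by more than
#' 10 dB.  The PTA uses the first 1 kHz run (the retest is a reliability
#' check, not an average).
#'
#' @param l a [listener].
#' @param config an [hw_config].
#' @param ear_order order of testing.
#' @return object of class `pta_exam`: measured [audiogram], `retest_1k`
#'   per ear, `reliable` per ear, `pta` per ear, `siegel` grades per ear,
#'   `ceiling` flag matrix.
#' @export
run_pta_exam <- function(l, config = hw_config(),
                         ear_order = c("right", "left")) {
  ear_order <- match.arg(ear_order, c("right", "left"), several.ok = TRUE)
  freqs <- sort(unique(config$freq_order))
  th <- matrix(NA_real_, 2, length(freqs),
               dimnames = list(c("left", "right"), freqs))
  ceil_flag <- matrix(FALSE, 2, length(freqs),
                      dimnames = dimnames(th))
  retest_1k <- c(left = NA_real_, right = NA_real_)
  for (e in ear_order) {
    for (f in config$freq_order) {
      r <- hughson_westlake_threshold(l, f, e, config)
      th[e, as.character(f)] <- r$threshold
      ceil_flag[e, as.character(f)] <- r$ceiling
    }
    retest_1k[e] <- hughson_westlake_threshold(l, 1000L, e, config)$threshold
  }
  reliable <- abs(retest_1k - th[, "1000"]) <= 10
  measured <- audiogram(left = th["left", ], right = th["right", ],
                        frequencies = freqs, reliable = reliable)
  pta <- c(left = compute_pta(measured, "left"),
           right = compute_pta(measured, "right"))
  structure(list(audiogram = measured, retest_1k = retest_1k,
                 reliable = reliable, pta = pta,
                 siegel = siegel_grade(pta), ceiling = ceil_flag),
            class = "pta_exam")
}

#' @export
print.pta_exam <- function(x, ...) {
  cat("Pure-tone audiometric exam (modified Hughson-Westlake)\n")
  print(x$audiogram)
  cat(sprintf("  1 kHz retest: left %g, right %g dB HL\n",
              x$retest_1k["left"], x$retest_1k["right"]))
  cat(sprintf("  PTA: left %.1f (grade %d), right %.1f (grade %d) dB HL\n",
              x$pta["left"], x$siegel["left"],
              x$pta["right"], x$siegel["right"]))
  if (!all(x$reliable)) {
    cat("  unreliable ear(s):",
        paste(names(x$reliable)[!x$reliable], collapse = ", "), "\n")
  }
  invisible(x)
}
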