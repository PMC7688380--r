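# Hearing Scale Test engine: adaptive per-ear search for the minimum
# audible hearing scale.
#
# Four pure tones (1, 2, 4, 0.5 kHz in fixed order) are presented at the
# current scale's level. If all four are heard the level descends one
# scale; any miss sends it up one scale. The result is the lowest scale at
# which all four tones were answered correctly, declared once that scale is
# bracketed by a recorded miss one scale below (or the floor S1 is fully
# heard). An ear that misses at S20 without any fully heard scale has no
# minimum audible scale (NO_RESPONSE).

#' Configuration of the Hearing Scale Test
#'
#' @param start_scale scale at which testing starts (default S5 = 25 dB HL).
#' @param freq_order presentation order of the four test frequencies
#'   (default 1, 2, 4, 0.5 kHz; must be a permutation of
#'   [HST_FREQUENCIES]).
#' @param tone_duration_s,isi_range_s stimulus timing metadata (1.5 s tones,
#'   2-3 s silent intervals); logged, not simulated in time.
#' @param max_presentations presentation cap; exceeding it marks the run
#'   invalid rather than guessing a scale (stochastic listeners can
#'   oscillate).
#' @param ambient_limit_dba ambient-noise gate in A-weighted dB; testing
#'   requires ambient noise strictly below this limit.
#' @param confirm_repeats extra confirmation blocks run at the candidate
#'   minimum audible scale before it is accepted (default 0: single
#'   determination, screening speed).
#' @return a list of class `hst_config`.
#' @export
hst_config <- function(start_scale = 5L,
                       freq_order = c(1000L, 2000L, 4000L, 500L),
                       tone_duration_s = 1.5,
                       isi_range_s = c(2, 3),
                       max_presentations = 60L,
                       ambient_limit_dba = 50,
                       confirm_repeats = 0L) {
  start_scale <- as.integer(start_scale)
  if (start_scale < 1L || start_scale > 20L) stop("start_scale must be in 1..20")
  freq_order <- as.integer(freq_order)
  if (!setequal(freq_order, HST_FREQUENCIES) ||
      length(freq_order) != length(HST_FREQUENCIES)) {
    stop("freq_order must be a permutation of the four HST frequencies")
  }
  structure(list(start_scale = start_scale, freq_order = freq_order,
                 tone_duration_s = tone_duration_s, isi_range_s = isi_range_s,
                 max_presentations = as.integer(max_presentations),
                 ambient_limit_dba = ambient_limit_dba,
                 confirm_repeats = as.integer(confirm_repeats)),
            class = "hst_config")
}

#' Ambient-noise gate
#'
#' Screening proceeds only if the measured background noise is strictly
#' below the limit (50 A-weighted dB by default).
#'
#' @param level_dba measured ambient level, dBA.
#' @param limit_dba gate limit, dBA.
#' @return logical: `TRUE` if testing may proceed.
#' @examples
#' ambient_noise_gate(49.9)  # TRUE
#' ambient_noise_gate(50)    # FALSE
#' @export
ambient_noise_gate <- function(level_dba, limit_dba = 50) {
  if (any(level_dba < 0)) stop("ambient level must be non-negative")
  level_dba < limit_dba
}

#' Run the Hearing Scale Test on one ear
#'
#' Presents the four test tones in `freq_order` at the current scale's dB HL
#' level; within a block, presentation stops at the first miss (the
#' all-correct requirement is already violated).  All four heard: descend
#' one scale; any miss: ascend one scale.  Terminates when the lowest
#' all-correct scale is bracketed by a recorded miss one scale below, or S1
#' is fully heard; a miss at S20 with no fully heard scale yields
#' [NO_RESPONSE].
#'
#' @param l a [listener].
#' @param ear `"left"` or `"right"`.
#' @param config an [hst_config].
#' @param ambient_dba ambient noise measured before testing (default 0,
#'   quiet room); the run refuses to start if the gate fails.
#' @return an object of class `hst_result`: list with `ear`,
#'   `min_audible_scale` (1..20, `NO_RESPONSE`, or `NA` if invalid),
#'   `valid`, `abort_reason`, `n_presentations`, and `trial_log`
#'   (data frame: scale, freq_hz, level_dbhl, response).
#' @examples
#' ag <- audiogram(left = c(20, 20, 20, 20), right = c(40, 50, 90, 83))
#' run_hst(listener(ag, deterministic = TRUE), "right")$min_audible_scale  # 18
#' @export
run_hst <- function(l, ear, config = hst_config(), ambient_dba = 0) {
  stopifnot(inherits(l, "listener"))
  ear <- match.arg(ear, c("left", "right"))
  if (!ambient_noise_gate(ambient_dba, config$ambient_limit_dba)) {
    stop("ambient noise gate failed: ", ambient_dba, " dBA >= ",
         config$ambient_limit_dba, " dBA")
  }
  # all HST frequencies must be present
  threshold_at(l$audiogram, ear, config$freq_order)

  ask <- .responder_for(l, ear)
  old <- if (!l$deterministic) .listener_rng_begin(l) else NULL
  if (!l$deterministic) on.exit(.listener_rng_end(l, old))

  log_scale <- integer(0); log_freq <- integer(0)
  log_level <- numeric(0); log_resp <- logical(0)
  n_pres <- 0L
  all_correct <- rep(FALSE, 20L)  # scale fully heard at some visit
  missed <- rep(FALSE, 20L)       # scale failed at some visit

  run_block <- function(s) {
    lev <- 5 * s
    heard_all <- TRUE
    for (f in config$freq_order) {
      r <- ask(lev, f)
      n_pres <<- n_pres + 1L
      log_scale <<- c(log_scale, s); log_freq <<- c(log_freq, f)
      log_level <<- c(log_level, lev); log_resp <<- c(log_resp, r)
      if (!r) { heard_all <- FALSE; break }
    }
    heard_all
  }

  finish <- function(scale, valid = TRUE, abort_reason = NA_character_) {
    structure(list(ear = ear, min_audible_scale = scale, valid = valid,
                   abort_reason = abort_reason, n_presentations = n_pres,
                   trial_log = data.frame(scale = log_scale,
                                          freq_hz = log_freq,
                                          level_dbhl = log_level,
                                          response = log_resp)),
              class = "hst_result")
  }

  confirm <- function(s) {
    if (config$confirm_repeats <= 0L) return(TRUE)
    for (i in seq_len(config$confirm_repeats)) {
      if (!run_block(s)) return(FALSE)
    }
    TRUE
  }

  s <- config$start_scale
  repeat {
    if (n_pres >= config$max_presentations) {
      return(finish(NA_integer_, valid = FALSE,
                    abort_reason = "max_presentations exceeded"))
    }
    if (run_block(s)) {
      all_correct[s] <- TRUE
      if (s == 1L || missed[s - 1L]) {
        if (confirm(s)) return(finish(s))
        all_correct[s] <- FALSE
        missed[s] <- TRUE
        if (s < 20L) s <- s + 1L
        next
      }
      s <- s - 1L
    } else {
      missed[s] <- TRUE
      if (s == 20L) {
        if (!any(all_correct)) return(finish(NO_RESPONSE))
        # stochastic corner: retest S20 until bracketed or capped
        next
      }
      if (all_correct[s + 1L]) {
        if (confirm(s + 1L)) return(finish(s + 1L))
        all_correct[s + 1L] <- FALSE
        missed[s + 1L] <- TRUE
      }
      s <- s + 1L
    }
  }
}

#' @export
print.hst_result <- function(x, ...) {
  cat("Hearing Scale Test result (", x$ear, " ear)\n", sep = "")
  if (!x$valid) {
    cat("  invalid run:", x$abort_reason, "\n")
  } else {
    cat("  minimum audible scale:", format_scale(x$min_audible_scale))
    if (!is_no_response(x$min_audible_scale)) {
      cat(" (", scale_to_db(x$min_audible_scale), " dB HL)", sep = "")
    }
    cat("\n")
  }
  cat("  presentations:", x$n_presentations, "\n")
  invisible(x)
}

#' Run the Hearing Scale Test on both ears
#'
#' Ears are tested sequentially (right first by default).  The worse ear
#' (higher scale, `NO_RESPONSE` counting as 21) is designated impaired and
#' the interaural scale difference is reported as impaired minus
#' contralateral.
#'
#' @inheritParams run_hst
#' @param ear_order order of testing.
#' @return list of class `hst_pair` with `right`, `left` ([run_hst]
#'   results), `impaired_ear`, and `scale_diff`.
#' @export
hst_both_ears <- function(l, config = hst_config(), ambient_dba = 0,
                          ear_order = c("right", "left")) {
  ear_order <- match.arg(ear_order, c("right", "left"), several.ok = TRUE)
  res <- list()
  for (e in ear_order) {
    res[[e]] <- run_hst(l, e, config = config, ambient_dba = ambient_dba)
  }
  sr <- res$right$min_audible_scale
  sl <- res$left$min_audible_scale
  if (is.na(sr) || is.na(sl)) {
    impaired <- NA_character_; sdiff <- NA_integer_
  } else {
    impaired <- if (sl > sr) "left" else "right"  # tie -> right
    sdiff <- abs(sr - sl)
  }
  structure(list(right = res$right, left = res$left,
                 impaired_ear = impaired, scale_diff = sdiff),
            class = "hst_pair")
}

#' @export
print.hst_pair <- function(x, ...) {
  cat("Hearing Scale Test, both ears\n")
  cat("  right:", format_scale(x$right$min_audible_scale),
      " left:", format_scale(x$left$min_audible_scale), "\n")
  cat("  impaired ear:", x$impaired_ear,
      " scale difference:", x$scale_diff, "\n")
  invisible(x)
}
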