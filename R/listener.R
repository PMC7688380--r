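# Virtual listener: answers heard / not-heard to a pure tone.
#
# Stochastic responses follow a logistic psychometric function with guess
# and lapse rates,
#   p(heard | level) = guess + (1 - guess - lapse) * F((level - t) / s),
# F the standard logistic CDF, t the true threshold, s the spread in dB.
# Each listener owns a private RNG stream, advanced once per presentation,
# so simulated procedures for one listener do not perturb another's draws.

#' Create a virtual listener
#'
#' A listener wraps a true [audiogram] and a psychometric response model.
#' In deterministic mode a tone is heard exactly when its level is at or
#' above the true threshold; in stochastic mode the response is Bernoulli
#' with probability given by a logistic psychometric function with guess and
#' lapse rates.
#'
#' @param audiogram true per-ear thresholds ([audiogram]).
#' @param slope_db spread of the logistic psychometric function in dB
#'   (default 3, a conventional pure-tone slope).
#' @param guess_rate probability of reporting an inaudible tone, in
#'   \[0, 0.5).
#' @param lapse_rate probability of missing a clearly audible tone, in
#'   \[0, 0.5).
#' @param deterministic if `TRUE`, respond by threshold comparison and
#'   ignore slope/guess/lapse.
#' @param seed integer seed of the listener's private random stream; if
#'   `NULL`, drawn from the ambient RNG (so a seeded caller still gets
#'   reproducible listeners).
#' @return an object of class `listener`.
#' @examples
#' ag <- audiogram(left = c(20, 20, 15, 10), right = c(83, 60, 55, 40))
#' l <- listener(ag, deterministic = TRUE)
#' respond(l, level = 85, freq = 1000, ear = "right")
#' @export
listener <- function(audiogram, slope_db = 3, guess_rate = 0.02,
                     lapse_rate = 0.02, deterministic = FALSE, seed = NULL) {
  stopifnot(inherits(audiogram, "audiogram"))
  if (slope_db <= 0) stop("slope_db must be positive")
  if (guess_rate < 0 || guess_rate >= 0.5) stop("guess_rate must be in [0, 0.5)")
  if (lapse_rate < 0 || lapse_rate >= 0.5) stop("lapse_rate must be in [0, 0.5)")
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
  }
  rng <- new.env(parent = emptyenv())
  old <- .hold_global_rng()
  set.seed(as.integer(seed))
  rng$state <- get(".Random.seed", envir = globalenv())
  .release_global_rng(old)
  structure(
    list(audiogram = audiogram, slope_db = slope_db,
         guess_rate = guess_rate, lapse_rate = lapse_rate,
         deterministic = isTRUE(deterministic), seed = as.integer(seed),
         rng = rng),
    class = "listener"
  )
}

#' @export
print.listener <- function(x, ...) {
  cat(if (x$deterministic) "Deterministic" else "Stochastic",
      "virtual listener\n")
  if (!x$deterministic) {
    cat(sprintf("  slope %.1f dB, guess %.3f, lapse %.3f, seed %d\n",
                x$slope_db, x$guess_rate, x$lapse_rate, x$seed))
  }
  print(x$audiogram)
  invisible(x)
}

.hold_global_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.release_global_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Swap the listener's private stream into the global RNG. Returns the held
# ambient state; pair with .listener_rng_end(). Procedures swap once per run
# so that per-presentation draws are cheap.
.listener_rng_begin <- function(l) {
  old <- .hold_global_rng()
  assign(".Random.seed", l$rng$state, envir = globalenv())
  old
}

.listener_rng_end <- function(l, old) {
  l$rng$state <- get(".Random.seed", envir = globalenv())
  .release_global_rng(old)
}

#' Psychometric response probability
#'
#' Probability that the listener reports hearing a tone at the given level.
#' Deterministic listeners return 0 or 1.
#'
#' @param l a [listener].
#' @param level stimulus level, dB HL (vectorised).
#' @param freq frequency in Hz.
#' @param ear `"left"` or `"right"`.
#' @return numeric vector of response probabilities.
#' @export
p_response <- function(l, level, freq, ear) {
  stopifnot(inherits(l, "listener"))
  t0 <- threshold_at(l$audiogram, ear, freq)
  if (l$deterministic) {
    return(as.numeric(level >= t0))
  }
  l$guess_rate + (1 - l$guess_rate - l$lapse_rate) *
    stats::plogis((level - t0) / l$slope_db)
}

#' Simulate one heard / not-heard response
#'
#' Draws one response from the listener's psychometric model, advancing the
#' listener's private random stream by one presentation (stochastic mode).
#'
#' @inheritParams p_response
#' @return logical: `TRUE` if the tone was heard.
#' @export
respond <- function(l, level, freq, ear) {
  stopifnot(inherits(l, "listener"), length(level) == 1L)
  t0 <- threshold_at(l$audiogram, ear, freq)
  if (l$deterministic) {
    return(level >= t0)
  }
  p <- l$guess_rate + (1 - l$guess_rate - l$lapse_rate) *
    stats::plogis((level - t0) / l$slope_db)
  old <- .listener_rng_begin(l)
  on.exit(.listener_rng_end(l, old))
  stats::runif(1) < p
}

# Fast per-procedure response closure: thresholds prefetched, draws taken
# from whatever stream is active (procedures swap the listener stream in
# around the whole run). Used internally by the staircase engines.
.responder_for <- function(l, ear) {
  th <- l$audiogram[ear, ]
  names(th) <- colnames(l$audiogram)
  if (l$deterministic) {
    function(level, freq) level >= th[[as.character(freq)]]
  } else {
    g <- l$guess_rate; lam <- l$lapse_rate; s <- l$slope_db
    function(level, freq) {
      p <- g + (1 - g - lam) * stats::plogis((level - th[[as.character(freq)]]) / s)
      stats::runif(1) < p
    }
  }
}
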