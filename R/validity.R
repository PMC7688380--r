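# Diagnostic-validity statistics: confusion tables, sensitivity /
# specificity / predictive values with exact binomial (Clopper-Pearson)
# intervals, Fisher-z correlation intervals, one-way ANOVA, and
# reconstruction of integer 2x2 tables from rounded printed percentages.

#' Construct a 2x2 confusion table
#'
#' Counts are laid out against the gold standard: `tp` screen+/gold+,
#' `fn` screen-/gold+, `fp` screen+/gold-, `tn` screen-/gold-.
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  x <- c(tp = as.integer(tp), fn = as.integer(fn),
         fp = as.integer(fp), tn = as.integer(tn))
  if (anyNA(x) || any(x < 0L)) stop("counts must be non-negative integers")
  structure(as.list(x), n = sum(x), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(screen = c("positive", "negative"),
                              gold = c("positive", "negative")))
  cat("Confusion table (n = ", attr(x, "n"), ")\n", sep = "")
  print(m)
  invisible(x)
}

#' Cross-tabulate screening records against the gold standard
#'
#' Recomputes the screen call at the given cutoff from each record's
#' interaural scale difference and tabulates it against the gold-standard
#' call.  Excluded records are dropped; records missing either call are an
#' error.
#'
#' @param records a [run_screening()] result (or any data frame with
#'   `scale_diff` and `gold_positive`, optionally `excluded`).
#' @param cutoff scale-difference cutoff.
#' @return a [confusion_table].
#' @export
confusion_from_records <- function(records, cutoff) {
  df <- as.data.frame(records)
  if (nrow(df) == 0L) stop("no records to tabulate")
  if (!is.null(df$excluded)) df <- df[!df$excluded, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records left after exclusions")
  bad <- is.na(df$scale_diff) | is.na(df$gold_positive)
  if (any(bad)) {
    stop("records missing screen or gold call: ",
         paste(df$subject_id[bad], collapse = ", "))
  }
  screen <- classify_ssnhl_by_scale(df$scale_diff, cutoff)
  gold <- df$gold_positive
  confusion_table(tp = sum(screen & gold), fn = sum(!screen & gold),
                  fp = sum(screen & !gold), tn = sum(!screen & !gold))
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided interval from beta quantiles:
#' lower = qbeta(alpha/2; x, n-x+1), upper = qbeta(1-alpha/2; x+1, n-x),
#' with lower 0 at x = 0 and upper 1 at x = n.  Coverage is conservative
#' (at least the nominal level).
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)` on the proportion scale.
#' @examples
#' clopper_pearson_ci(64, 67)  # 0.875, 0.991
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  x <- as.integer(x); n <- as.integer(n)
  if (is.na(x) || is.na(n) || n <= 0L || x < 0L || x > n) {
    stop("need 0 <= x <= n with n > 0")
  }
  a <- (1 - level) / 2
  lower <- if (x == 0L) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Diagnostic metrics with exact confidence intervals
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive
#' value tp/(tp+fp), negative predictive value tn/(tn+fn), each with a
#' Clopper-Pearson interval.  A metric with a zero denominator is returned
#' as `NA` and flagged.
#'
#' @param tab a [confusion_table].
#' @param level confidence level.
#' @return object of class `diagnostic_summary`: data frame with columns
#'   `metric`, `numerator`, `denominator`, `estimate`, `lower`, `upper`.
#' @export
diagnostic_metrics <- function(tab, level = 0.95) {
  stopifnot(inherits(tab, "confusion_table"))
  num <- c(sensitivity = tab$tp, specificity = tab$tn,
           ppv = tab$tp, npv = tab$tn)
  den <- c(sensitivity = tab$tp + tab$fn, specificity = tab$tn + tab$fp,
           ppv = tab$tp + tab$fp, npv = tab$tn + tab$fn)
  rows <- lapply(names(num), function(m) {
    if (den[m] == 0L) {
      data.frame(metric = m, numerator = num[[m]], denominator = den[[m]],
                 estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    } else {
      ci <- clopper_pearson_ci(num[[m]], den[[m]], level)
      data.frame(metric = m, numerator = num[[m]], denominator = den[[m]],
                 estimate = num[[m]] / den[[m]],
                 lower = ci[["lower"]], upper = ci[["upper"]])
    }
  })
  out <- do.call(rbind, rows)
  structure(out, level = level, class = c("diagnostic_summary", "data.frame"))
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("Diagnostic validity (%.0f%% exact CIs)\n",
              100 * attr(x, "level")))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("  %-12s undefined (zero denominator)\n", x$metric[i]))
    } else {
      cat(sprintf("  %-12s %5.1f%% (%d/%d, CI %.1f-%.1f)\n", x$metric[i],
                  100 * x$estimate[i], x$numerator[i], x$denominator[i],
                  100 * x$lower[i], 100 * x$upper[i]))
    }
  }
  invisible(x)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Either computes r from paired data or takes a reported `r` and `n`
#' directly (CI-only entry point).  The interval is
#' tanh(atanh(r) +/- z * 1/sqrt(n-3)).
#'
#' @param x,y numeric vectors (equal length >= 4), or `NULL` when `r` and
#'   `n` are given.
#' @param r,n reported correlation and sample size (alternative to data).
#' @param level confidence level.
#' @return list with `r`, `lower`, `upper`, `n`, and `degenerate` (TRUE
#'   when |r| = 1 and the interval collapses).
#' @examples
#' pearson_r_with_ci(r = 0.88, n = 88)  # CI 0.82-0.92
#' @export
pearson_r_with_ci <- function(x = NULL, y = NULL, r = NULL, n = NULL,
                              level = 0.95) {
  if (is.null(r)) {
    stopifnot(length(x) == length(y))
    if (length(x) < 4L) stop("need at least 4 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("zero variance in x or y")
    }
    r <- stats::cor(x, y)
    n <- length(x)
  }
  stopifnot(n >= 4L, abs(r) <= 1)
  if (abs(r) >= 1 - 1e-12) {
    return(list(r = r, lower = r, upper = r, n = n, degenerate = TRUE))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(r = r, lower = tanh(z - q * se), upper = tanh(z + q * se), n = n,
       degenerate = FALSE)
}

#' Classical one-way fixed-effects ANOVA
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return list with `F`, `p`, `df` (numerator, denominator degrees of
#'   freedom).
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("each group needs at least 2 values")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  Fv <- unname(fit$statistic)
  if (is.nan(Fv)) Fv <- 0  # identical groups: no variance anywhere
  p <- unname(fit$p.value)
  if (is.nan(p)) p <- 1
  list(F = Fv, p = p, df = unname(fit$parameter))
}

.round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

# A computed proportion "matches" a printed 1-dp percentage if either
# half-up rounding or truncation of 100*m reproduces it (published tables
# mix the two conventions).
.matches_printed1 <- function(m, printed) {
  v <- m * 100
  abs(.round_half_up1(v) - printed) < 1e-9 |
    abs(floor(v * 10) / 10 - printed) < 1e-9
}

#' Reconstruct the integer 2x2 table behind rounded printed percentages
#'
#' Exhaustively searches all integer tables (tp, fn, fp, tn) summing to
#' `n_total` and returns the unique one whose sensitivity, specificity,
#' PPV and NPV reproduce the four printed percentages at 1 decimal.  Zero
#' or multiple solutions are an error (listing candidates).
#'
#' @param sensitivity,specificity,ppv,npv printed percentages (1 decimal).
#' @param n_total total sample size.
#' @return a [confusion_table].
#' @examples
#' reconstruct_counts(95.5, 66.7, 90.1, 82.3, 88)  # tp 64, fn 3, fp 7, tn 14
#' @export
reconstruct_counts <- function(sensitivity, specificity, ppv, npv, n_total) {
  n <- as.integer(n_total)
  stopifnot(n >= 2L)
  # sensitivity and NPV fix (tp, fn) candidates; fp/tn fill the rest
  cand <- NULL
  for (tp in 0:n) for (fn in 0:(n - tp)) {
    pos <- tp + fn
    if (pos == 0L || pos == n) next
    if (!.matches_printed1(tp / pos, sensitivity)) next
    fp <- 0:(n - pos)
    tn <- n - pos - fp
    keep <- (fp + tn) > 0L & (tp + fp) > 0L & (tn + fn) > 0L &
      .matches_printed1(tn / (tn + fp), specificity) &
      .matches_printed1(tp / (tp + fp), ppv) &
      .matches_printed1(tn / (tn + fn), npv)
    if (any(keep)) {
      cand <- rbind(cand, cbind(tp = tp, fn = fn,
                                fp = fp[keep], tn = tn[keep]))
    }
  }
  if (is.null(cand) || nrow(cand) == 0L) {
    stop("no integer table reproduces the printed percentages at n = ", n)
  }
  if (nrow(cand) > 1L) {
    stop("printed percentages are ambiguous; candidate tables: ",
         paste(apply(cand, 1, paste, collapse = "/"), collapse = "; "))
  }
  confusion_table(cand[1, "tp"], cand[1, "fn"], cand[1, "fp"], cand[1, "tn"])
}

#' Validity table across scale-difference cutoffs
#'
#' One row per cutoff with the four diagnostic metrics and their exact 95%
#' intervals, shaped like a published validity table.
#'
#' @param records a [run_screening()] result.
#' @param cutoffs integer cutoffs (default 5:7).
#' @param level confidence level.
#' @return data frame with columns `cutoff`, `db_equivalent`, and for each
#'   metric its estimate and interval bounds (percent).
#' @export
validity_table <- function(records, cutoffs = 5:7, level = 0.95) {
  rows <- lapply(cutoffs, function(k) {
    dm <- diagnostic_metrics(confusion_from_records(records, k), level)
    vals <- as.vector(t(as.matrix(dm[, c("estimate", "lower", "upper")])))
    names(vals) <- paste0(rep(dm$metric, each = 3),
                          c("", "_lower", "_upper"))
    data.frame(cutoff = k, db_equivalent = 5 * k,
               as.list(100 * vals), check.names = FALSE)
  })
  do.call(rbind, rows)
}
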