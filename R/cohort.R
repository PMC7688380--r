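# Seeded generator of virtual referral cohorts with the statistical
# structure of a tertiary-care SSNHL sample: 88 adults, half female, mean
# age 46 (SD 14.7), worst-ear Siegel-grade mixture 8/9/49/18/16%, and a
# gold-standard prevalence of 67/88.
#
# Sampling scheme per subject: draw a Siegel grade (stratified to exact
# counts), a target impaired-ear PTA uniform within that grade's interval,
# per-frequency thresholds = target + loss-shape offsets + jitter,
# re-centred so the PTA is exact; the contralateral ear's PTA is a
# truncated normal further conditioned on the subject's stratified
# gold-standard label, so prevalence is controlled without breaking the
# marginal. Truth labels are then recomputed from the final audiograms.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the referral cohort the screening validity study
#' describes; every field is overridable.
#'
#' @param n cohort size (default 88).
#' @param seed generator seed.
#' @param female_prop proportion female (default 0.5, assigned to exact
#'   counts by largest remainder).
#' @param age_mean,age_sd,age_range age distribution in years (normal,
#'   truncated).
#' @param grade_mix worst-ear modified-Siegel grade mixture, grades 1..5
#'   (default 8/9/49/18/16%, stratified to exact counts).
#' @param grade_intervals 5 x 2 matrix of PTA sampling intervals per grade,
#'   dB HL.
#' @param gold_positive_prop target prevalence of the gold-standard SSNHL
#'   label (default 67/88, derived from the reconstructed validity tables).
#' @param gold_cutoff_db interaural PTA difference defining the label.
#' @param contra_mean,contra_sd,contra_range contralateral-ear PTA model:
#'   normal, truncated (default mean 15, sd 7, range \[-10, 60\] dB HL).
#' @param jitter_sd within-ear per-frequency jitter SD, dB.
#' @param shape_flat_prop proportion of flat (vs down-sloping) impaired-ear
#'   loss shapes.
#' @param slope_tilt_db high-frequency tilt of the down-sloping shape at
#'   2 and 4 kHz, dB (re-centred before use).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n = 88L, seed = 1L, female_prop = 0.5,
                          age_mean = 46, age_sd = 14.7,
                          age_range = c(18, 90),
                          grade_mix = c(0.08, 0.09, 0.49, 0.18, 0.16),
                          grade_intervals = rbind(c(0, 25), c(25, 45),
                                                  c(45, 75), c(75, 90),
                                                  c(90, 120)),
                          gold_positive_prop = 67 / 88,
                          gold_cutoff_db = 30,
                          contra_mean = 15, contra_sd = 7,
                          contra_range = c(-10, 60),
                          jitter_sd = 4, shape_flat_prop = 0.7,
                          slope_tilt_db = c(10, 20)) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  if (abs(sum(grade_mix) - 1) > 1e-9) stop("grade_mix must sum to 1")
  if (any(grade_mix < 0) || female_prop < 0 || female_prop > 1 ||
      gold_positive_prop < 0 || gold_positive_prop > 1) {
    stop("proportions must lie in [0, 1]")
  }
  if (any(grade_intervals[, 2] <= grade_intervals[, 1])) {
    stop("each grade interval must be non-empty")
  }
  structure(list(n = n, seed = as.integer(seed), female_prop = female_prop,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 grade_mix = grade_mix, grade_intervals = grade_intervals,
                 gold_positive_prop = gold_positive_prop,
                 gold_cutoff_db = gold_cutoff_db,
                 contra_mean = contra_mean, contra_sd = contra_sd,
                 contra_range = contra_range, jitter_sd = jitter_sd,
                 shape_flat_prop = shape_flat_prop,
                 slope_tilt_db = slope_tilt_db),
            class = "cohort_config")
}

# Largest-remainder apportionment of n into round(n * p) integer counts.
.largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) {
    # essentially no normal mass in the interval: fall back to uniform
    return(stats::runif(n, lo, hi))
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Per-frequency thresholds with exact mean `target`, clamped to bounds.
# Clamping deficits are redistributed over the unclamped frequencies.
.thresholds_for_pta <- function(target, offsets, jitter_sd, lo, hi) {
  th <- target + offsets + stats::rnorm(length(offsets), 0, jitter_sd)
  for (it in 1:50) {
    th <- th + (target - mean(th))
    cl <- pmin(pmax(th, lo), hi)
    if (max(abs(cl - th)) < 1e-12 && abs(mean(cl) - target) < 1e-9) {
      return(cl)
    }
    free <- cl > lo & cl < hi
    if (!any(free)) return(cl)
    cl[free] <- cl[free] + (target - mean(cl)) * length(cl) / sum(free)
    th <- cl
  }
  pmin(pmax(th, lo), hi)
}

#' Generate a synthetic referral cohort
#'
#' Reproducible given the seed.  Sex and grade are assigned to exact counts
#' by largest remainder; the gold-standard SSNHL label is stratified to the
#' target prevalence and assigned to the subjects with the highest
#' impaired-ear PTAs (where an interaural difference of the required size
#' is feasible), then recomputed from the final audiograms so labels and
#' audiograms can never disagree.  Bilateral and conductive loss flags are
#' always `FALSE`: the generator emulates the post-exclusion analysis
#' cohort.
#'
#' @param config a [cohort_config].
#' @param seed overrides `config$seed` if given.
#' @return object of class `hs_cohort`: list with `subjects` (list, one per
#'   subject: id, age, sex, impaired ear side, grade, [audiogram], truth
#'   labels) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  old <- .hold_global_rng()
  on.exit(.release_global_rng(old))
  set.seed(config$seed)
  n <- config$n

  sex_counts <- .largest_remainder(c(config$female_prop,
                                     1 - config$female_prop), n)
  sex <- sample(rep(c("female", "male"), sex_counts))
  age <- round(.rtruncnorm(n, config$age_mean, config$age_sd,
                           config$age_range[1], config$age_range[2]))
  grade_counts <- .largest_remainder(config$grade_mix, n)
  grade <- sample(rep(1:5, grade_counts))
  pta_imp <- stats::runif(n, config$grade_intervals[grade, 1],
                          config$grade_intervals[grade, 2])
  impaired_side <- sample(c("left", "right"), n, replace = TRUE)

  # stratified gold label: positives need contralateral PTA <= PTA - cutoff,
  # feasible only when that bound is inside the contralateral range
  n_pos <- .largest_remainder(c(config$gold_positive_prop,
                                1 - config$gold_positive_prop), n)[1]
  feasible <- (pta_imp - config$gold_cutoff_db) >= config$contra_range[1]
  ord <- order(pta_imp, decreasing = TRUE)
  pos_ids <- ord[feasible[ord]][seq_len(min(n_pos, sum(feasible)))]
  intended_pos <- seq_len(n) %in% pos_ids

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    # contralateral PTA conditioned on the intended label
    if (intended_pos[i]) {
      lo <- config$contra_range[1]
      hi <- min(config$contra_range[2], pta_imp[i] - config$gold_cutoff_db)
    } else {
      lo <- max(config$contra_range[1],
                pta_imp[i] - config$gold_cutoff_db + 1e-6)
      # the impaired ear stays the worse ear even for gold negatives
      hi <- min(config$contra_range[2], pta_imp[i])
      if (lo >= hi) { # negative label infeasible: subject becomes positive
        lo <- config$contra_range[1]
        hi <- min(config$contra_range[2], pta_imp[i] - config$gold_cutoff_db)
      }
    }
    pta_con <- .rtruncnorm(1, config$contra_mean, config$contra_sd, lo, hi)

    flat <- stats::runif(1) < config$shape_flat_prop
    offsets <- if (flat) rep(0, 4) else {
      o <- c(0, 0, config$slope_tilt_db[1], config$slope_tilt_db[2])
      o - mean(o)
    }
    th_imp <- .thresholds_for_pta(pta_imp[i], offsets, config$jitter_sd,
                                  -10, 120)
    th_con <- .thresholds_for_pta(pta_con, rep(0, 4), config$jitter_sd,
                                  config$contra_range[1],
                                  config$contra_range[2])
    if (impaired_side[i] == "left") {
      ag <- audiogram(left = th_imp, right = th_con)
    } else {
      ag <- audiogram(left = th_con, right = th_imp)
    }
    pta_imp_final <- compute_pta(ag, impaired_side[i])
    pta_con_final <- compute_pta(ag, setdiff(c("left", "right"),
                                             impaired_side[i]))
    subjects[[i]] <- list(
      subject_id = i, age = age[i], sex = sex[i],
      impaired_ear = impaired_side[i], grade = grade[i],
      audiogram = ag,
      pta_impaired_true = pta_imp_final,
      pta_contra_true = pta_con_final,
      gold_positive = gold_standard_ssnhl(pta_imp_final, pta_con_final,
                                          config$gold_cutoff_db),
      onset_within_72h = TRUE,
      bilateral_loss = FALSE, conductive_loss = FALSE)
  }
  structure(list(subjects = subjects, config = config), class = "hs_cohort")
}

#' @export
print.hs_cohort <- function(x, ...) {
  cat("Synthetic referral cohort: n =", length(x$subjects),
      "(seed", paste0(x$config$seed, ")\n"))
  cat("  gold-standard positive:",
      sum(vapply(x$subjects, `[[`, TRUE, "gold_positive")), "\n")
  invisible(x)
}

#' Summarise a cohort in the shape of a baseline-characteristics table
#'
#' Means, SDs and percentages for age, sex, worst-ear Siegel grade, PTA of
#' the worst ear, and interaural PTA differences; when a
#' [run_screening()] result is supplied, the worst-ear hearing scale and
#' interaural scale difference rows are added.
#'
#' @param cohort an [generate_cohort()] cohort.
#' @param screening optional `screening_result` for the scale rows.
#' @return data frame with columns `variable`, `value`, `spread`.
#' @export
summarize_cohort <- function(cohort, screening = NULL) {
  stopifnot(inherits(cohort, "hs_cohort"))
  s <- cohort$subjects
  if (!length(s)) stop("cohort is empty")
  get <- function(f) vapply(s, `[[`, s[[1]][[f]], f)
  age <- get("age")
  pta_imp <- get("pta_impaired_true")
  pta_diff <- pta_imp - get("pta_contra_true")
  grade <- factor(get("grade"), levels = 1:5)
  rows <- data.frame(
    variable = c("age_years", "female", paste0("grade_", 1:5),
                 "pta_worst_ear_db", "pta_difference_db"),
    value = c(mean(age), 100 * mean(get("sex") == "female"),
              100 * as.numeric(prop.table(table(grade))),
              mean(pta_imp), mean(pta_diff)),
    spread = c(stats::sd(age), sum(get("sex") == "female"),
               as.numeric(table(grade)),
               stats::sd(pta_imp), stats::sd(pta_diff)))
  if (!is.null(screening)) {
    inc <- !screening$excluded
    rows <- rbind(rows, data.frame(
      variable = c("scale_worst_ear", "scale_difference"),
      value = c(mean(screening$scale_impaired[inc], na.rm = TRUE),
                mean(screening$scale_diff[inc], na.rm = TRUE)),
      spread = c(stats::sd(screening$scale_impaired[inc], na.rm = TRUE),
                 stats::sd(screening$scale_diff[inc], na.rm = TRUE))))
  }
  rows
}
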