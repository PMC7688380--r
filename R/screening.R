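# Triage and decision layer: group assignment from per-ear scales,
# referral, the scale-difference SSNHL screen, the PTA-difference gold
# standard, and the end-to-end cohort pipeline.

#' Decision configuration for the screening workflow
#'
#' @param scale_cutoff interaural scale difference at or above which the
#'   screen calls SSNHL (default 5 scales = 25 dB).
#' @param gold_cutoff_db interaural PTA difference defining the
#'   gold-standard positive (default 30 dB).
#' @param referral_scale worse-ear scale above which the subject is
#'   referred (default S10).
#' @param referral_diff scale difference at or above which the subject is
#'   referred (default 5).
#' @param exam_all run the conventional exam on every subject (default
#'   `TRUE`, as in a validity study); if `FALSE`, only referred subjects
#'   are examined and the others carry no gold-standard call.
#' @param exclude_unreliable drop subjects whose exam fails the 1 kHz
#'   retest check from the analysis set (default `FALSE`: include, flag).
#' @return list of class `decision_config`.
#' @export
decision_config <- function(scale_cutoff = 5L, gold_cutoff_db = 30,
                            referral_scale = 10L, referral_diff = 5L,
                            exam_all = TRUE, exclude_unreliable = FALSE) {
  scale_cutoff <- as.integer(scale_cutoff)
  if (scale_cutoff < 1L || scale_cutoff > 20L) {
    stop("scale_cutoff must be in 1..20")
  }
  structure(list(scale_cutoff = scale_cutoff,
                 gold_cutoff_db = gold_cutoff_db,
                 referral_scale = as.integer(referral_scale),
                 referral_diff = as.integer(referral_diff),
                 exam_all = isTRUE(exam_all),
                 exclude_unreliable = isTRUE(exclude_unreliable)),
            class = "decision_config")
}

#' Triage from the per-ear Hearing Scale Test results
#'
#' The worse ear's scale assigns one of three groups (<=S5, S6-S10, >S10;
#' `NO_RESPONSE` counts above S10).  A subject is referred for
#' comprehensive assessment if the worse scale exceeds S10 or the
#' interaural scale difference reaches the referral cutoff (>= 5 scales).
#'
#' @param scale_right,scale_left per-ear minimum audible scales
#'   (21 = `NO_RESPONSE`).
#' @param config a [decision_config].
#' @return list with `group` (factor), `referred`, `worse_scale`,
#'   `scale_diff`.
#' @examples
#' triage(12, 6)  # worse ear >S10: referred
#' triage(9, 4)   # 5-scale difference: referred
#' @export
triage <- function(scale_right, scale_left, config = decision_config()) {
  s <- as.integer(c(scale_right, scale_left))
  stopifnot(all(s >= 1L & s <= NO_RESPONSE))
  worse <- max(s)
  diff <- abs(s[1] - s[2])
  group <- if (worse <= 5L) "<=S5" else if (worse <= 10L) "S6-S10" else ">S10"
  list(group = factor(group, levels = c("<=S5", "S6-S10", ">S10")),
       referred = worse > config$referral_scale || diff >= config$referral_diff,
       worse_scale = worse, scale_diff = diff)
}

#' Scale-difference SSNHL screen
#'
#' Positive when the interaural scale difference (impaired minus
#' contralateral, `NO_RESPONSE` as 21) is at or above the cutoff.
#'
#' @param scale_diff integer scale difference (vectorised).
#' @param cutoff cutoff in scales (default 5 = 25 dB).
#' @return logical vector.
#' @export
classify_ssnhl_by_scale <- function(scale_diff, cutoff = 5L) {
  scale_diff >= cutoff
}

#' Gold-standard SSNHL call from pure-tone averages
#'
#' Positive when the PTA of the impaired ear exceeds the contralateral PTA
#' by at least the cutoff (30 dB).
#'
#' @param pta_impaired,pta_contra PTAs in dB HL (vectorised).
#' @param cutoff_db gold-standard cutoff, dB (default 30).
#' @return logical vector.
#' @export
gold_standard_ssnhl <- function(pta_impaired, pta_contra, cutoff_db = 30) {
  (pta_impaired - pta_contra) >= cutoff_db
}

#' Run the full screening pipeline on a cohort
#'
#' For each subject: ambient gate, Hearing Scale Test on both ears, triage
#' and referral, conventional pure-tone exam (all subjects by default, as
#' in a validity study), gold-standard call from the exam PTAs, and the
#' scale-difference screen at each requested cutoff.  The impaired ear is
#' the one with the higher scale (ties broken by higher exam PTA, then
#' right).  Subjects labelled with bilateral or conductive loss are
#' excluded from the analysis set, as are per-subject failures (flagged,
#' run continues).
#'
#' @param cohort an [generate_cohort()] cohort, or a list of [listener]
#'   objects.
#' @param cutoffs scale-difference cutoffs to evaluate (default 5:7).
#' @param listener_args list of arguments passed to [listener()] when the
#'   cohort carries audiograms (`slope_db`, `guess_rate`, `lapse_rate`,
#'   `deterministic`).
#' @param hst an [hst_config]; `hw` an [hw_config]; `decision` a
#'   [decision_config].
#' @param hw,decision see above.
#' @param ambient_dba ambient noise at testing, dBA.
#' @param seed seed for the per-subject listener streams (ignored for
#'   deterministic listeners).
#' @return object of class `screening_result`: a data frame with one row
#'   per subject (scales, PTAs, differences, triage, referral, gold and
#'   screen calls per cutoff, exclusion flags), with the configuration in
#'   attributes.
#' @export
run_screening <- function(cohort, cutoffs = 5:7,
                          listener_args = list(deterministic = TRUE),
                          hst = hst_config(), hw = hw_config(),
                          decision = decision_config(),
                          ambient_dba = 0, seed = 1L) {
  subjects <- .as_subject_list(cohort)
  n <- length(subjects)
  if (n == 0L) stop("cohort is empty")
  cutoffs <- sort(as.integer(cutoffs))

  old_seed <- .hold_global_rng()
  on.exit(.release_global_rng(old_seed))
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(.Machine$integer.max, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    row <- list(subject_id = s$subject_id, age = s$age, sex = s$sex,
                scale_right = NA_integer_, scale_left = NA_integer_,
                impaired_ear = NA_character_,
                scale_impaired = NA_integer_, scale_contra = NA_integer_,
                scale_diff = NA_integer_,
                pta_right = NA_real_, pta_left = NA_real_,
                pta_impaired = NA_real_, pta_contra = NA_real_,
                pta_diff = NA_real_,
                reliable_right = NA, reliable_left = NA,
                triage_group = NA_character_, referred = NA,
                gold_positive = NA,
                excluded = FALSE, exclusion_reason = NA_character_)
    for (k in cutoffs) row[[paste0("screen_cut", k)]] <- NA

    if (isTRUE(s$bilateral_loss)) {
      row$excluded <- TRUE; row$exclusion_reason <- "bilateral loss"
    } else if (isTRUE(s$conductive_loss)) {
      row$excluded <- TRUE; row$exclusion_reason <- "conductive loss"
    }

    ok <- try({
      l <- if (inherits(s$listener, "listener")) s$listener else
        do.call(listener, c(list(audiogram = s$audiogram,
                                 seed = subject_seeds[i]), listener_args))
      pair <- hst_both_ears(l, config = hst, ambient_dba = ambient_dba)
      row$scale_right <- pair$right$min_audible_scale
      row$scale_left <- pair$left$min_audible_scale
      tri <- triage(row$scale_right, row$scale_left, decision)
      row$triage_group <- as.character(tri$group)
      row$referred <- tri$referred

      exam <- NULL
      if (decision$exam_all || tri$referred) {
        exam <- run_pta_exam(l, config = hw)
        row$pta_right <- exam$pta[["right"]]
        row$pta_left <- exam$pta[["left"]]
        row$reliable_right <- exam$reliable[["right"]]
        row$reliable_left <- exam$reliable[["left"]]
      }

      # impaired ear: higher scale; tie -> higher exam PTA; tie -> right
      imp <- if (row$scale_left > row$scale_right) "left"
        else if (row$scale_right > row$scale_left) "right"
        else if (!is.null(exam) && exam$pta[["left"]] > exam$pta[["right"]])
          "left" else "right"
      con <- if (imp == "left") "right" else "left"
      row$impaired_ear <- imp
      row$scale_impaired <- row[[paste0("scale_", imp)]]
      row$scale_contra <- row[[paste0("scale_", con)]]
      row$scale_diff <- row$scale_impaired - row$scale_contra

      if (!is.null(exam)) {
        row$pta_impaired <- exam$pta[[imp]]
        row$pta_contra <- exam$pta[[con]]
        row$pta_diff <- row$pta_impaired - row$pta_contra
        row$gold_positive <- gold_standard_ssnhl(row$pta_impaired,
                                                 row$pta_contra,
                                                 decision$gold_cutoff_db)
        if (decision$exclude_unreliable && !all(exam$reliable) &&
            !row$excluded) {
          row$excluded <- TRUE
          row$exclusion_reason <- "unreliable exam"
        }
      }
      for (k in cutoffs) {
        row[[paste0("screen_cut", k)]] <-
          classify_ssnhl_by_scale(row$scale_diff, k)
      }
      TRUE
    }, silent = TRUE)
    if (inherits(ok, "try-error")) {
      row$excluded <- TRUE
      row$exclusion_reason <- paste("failed:",
                                    conditionMessage(attr(ok, "condition")))
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, cutoffs = cutoffs, decision = decision, seed = seed,
            class = c("screening_result", "data.frame"))
}

.as_subject_list <- function(cohort) {
  if (inherits(cohort, "hs_cohort")) return(cohort$subjects)
  if (inherits(cohort, "listener")) cohort <- list(cohort)
  stopifnot(is.list(cohort))
  lapply(seq_along(cohort), function(i) {
    x <- cohort[[i]]
    if (inherits(x, "listener")) {
      list(subject_id = i, age = NA_real_, sex = NA_character_,
           audiogram = x$audiogram, listener = x,
           bilateral_loss = FALSE, conductive_loss = FALSE)
    } else if (inherits(x, "audiogram")) {
      list(subject_id = i, age = NA_real_, sex = NA_character_,
           audiogram = x, bilateral_loss = FALSE, conductive_loss = FALSE)
    } else x
  })
}

#' @export
print.screening_result <- function(x, ...) {
  inc <- !x$excluded
  cat("Screening pipeline results: ", nrow(x), " subjects (",
      sum(!inc), " excluded)\n", sep = "")
  cat("  referred:", sum(x$referred[inc], na.rm = TRUE),
      " gold-positive:", sum(x$gold_positive[inc], na.rm = TRUE), "\n")
  for (k in attr(x, "cutoffs")) {
    cat(sprintf("  screen positive at %d scales: %d\n", k,
                sum(x[[paste0("screen_cut", k)]][inc], na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.screening_result <- function(object, ...) {
  validity_table(object, cutoffs = attr(object, "cutoffs"))
}
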