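# Plain-text interchange: audiograms and exam results as CSV, listener
# parameters and HST results as JSON. CSV columns follow the
# subject_id / ear / freq_hz / threshold_dbhl convention throughout.

#' Write audiograms to CSV
#'
#' Long format: `subject_id, ear, freq_hz, threshold_dbhl`.
#'
#' @param x a named list of [audiogram] objects (names = subject ids), a
#'   single audiogram, or an [generate_cohort()] cohort.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_audiograms <- function(x, path) {
  if (inherits(x, "audiogram")) x <- list(`1` = x)
  if (inherits(x, "hs_cohort")) {
    ags <- lapply(x$subjects, `[[`, "audiogram")
    names(ags) <- vapply(x$subjects, `[[`, 1L, "subject_id")
    x <- ags
  }
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "audiogram")))
  ids <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
  rows <- lapply(seq_along(x), function(i) {
    ag <- x[[i]]
    expand <- expand.grid(ear = rownames(ag),
                          freq_hz = as.integer(colnames(ag)),
                          stringsAsFactors = FALSE)
    data.frame(subject_id = ids[i], expand,
               threshold_dbhl = ag[cbind(expand$ear,
                                         as.character(expand$freq_hz))])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read audiograms from CSV
#'
#' @param path file written by [write_audiograms()] (columns `subject_id`,
#'   `ear`, `freq_hz`, `threshold_dbhl`).
#' @return named list of [audiogram] objects.
#' @export
read_audiograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "ear", "freq_hz", "threshold_dbhl")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$subject_id), function(d) {
    freqs <- sort(unique(d$freq_hz))
    grab <- function(e) {
      dd <- d[d$ear == e, ]
      stats::setNames(dd$threshold_dbhl, dd$freq_hz)[as.character(freqs)]
    }
    audiogram(left = grab("left"), right = grab("right"),
              frequencies = freqs)
  })
  out[order(as.numeric(names(out)))]
}

#' Read listeners from an audiogram CSV plus optional parameter JSON
#'
#' The JSON file may carry `slope_db`, `guess_rate`, `lapse_rate`,
#' `deterministic` and `seed`, applied to every listener.
#'
#' @param audiogram_path audiogram CSV ([read_audiograms()]).
#' @param params_path optional JSON file of listener parameters.
#' @return named list of [listener] objects.
#' @export
read_listeners <- function(audiogram_path, params_path = NULL) {
  ags <- read_audiograms(audiogram_path)
  params <- if (is.null(params_path)) list() else
    jsonlite::fromJSON(params_path)
  allowed <- c("slope_db", "guess_rate", "lapse_rate", "deterministic",
               "seed")
  params <- params[intersect(names(params), allowed)]
  lapply(ags, function(ag) do.call(listener, c(list(audiogram = ag), params)))
}

#' Serialise an HST result to JSON
#'
#' @param x an `hst_result` from [run_hst()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hst_result <- function(x, path) {
  stopifnot(inherits(x, "hst_result"))
  out <- list(ear = x$ear,
              min_audible_scale = format_scale(x$min_audible_scale),
              valid = x$valid, abort_reason = x$abort_reason,
              n_presentations = x$n_presentations,
              trial_log = x$trial_log)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write and read screening results as CSV
#'
#' @param x a `screening_result` from [run_screening()].
#' @param path file path.
#' @return `path` (write) or a data frame (read).
#' @export
write_screening_results <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screening_results
#' @export
read_screening_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write and read RETSPL / output tables as CSV
#'
#' Two-column CSV `freq_hz, value_db`.
#'
#' @param x a [retspl_table] or named numeric vector.
#' @param path file path.
#' @return `path` (write) or a [retspl_table] (read).
#' @export
write_freq_table <- function(x, path) {
  if (inherits(x, "retspl")) {
    df <- data.frame(freq_hz = x$freq_hz, value_db = x$offset_db)
  } else {
    df <- data.frame(freq_hz = as.integer(names(x)), value_db = as.numeric(x))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_freq_table
#' @export
read_freq_table <- function(path) {
  df <- utils::read.csv(path)
  retspl_table(df$freq_hz, df$value_db)
}
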