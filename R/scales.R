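#' @title Hearing-scale grid and audiometric core
#' @description
#' The Hearing Scale Test (HST) expresses hearing level on 20 stratified
#' scales 5 dB apart, anchored at scale 5 (S5) = 25 dB HL, so scale k
#' corresponds to 5k dB HL (S1 = 5, S17 = 85, S20 = 100 dB HL).  An ear in
#' which even the loudest scale is not heard at every test frequency has no
#' minimum audible scale; this is the `NO_RESPONSE` sentinel, which for
#' difference arithmetic is treated as one scale above S20 (numeric 21).
#' @name hearing-scales
NULL

#' Test frequencies of the Hearing Scale Test and pure-tone average
#'
#' The HST and the four-frequency pure-tone average (PTA) use 0.5, 1, 2 and
#' 4 kHz; device calibration extends to 0.25 and 8 kHz.
#'
#' @format Integer vectors of frequencies in Hz.
#' @export
HST_FREQUENCIES <- c(500L, 1000L, 2000L, 4000L)

#' @rdname HST_FREQUENCIES
#' @export
CALIBRATION_FREQUENCIES <- c(250L, 500L, 1000L, 2000L, 4000L, 8000L)

#' No-response sentinel for the hearing scale
#'
#' An ear that fails every scale up to S20 has no minimum audible scale.
#' The sentinel compares greater than any valid index and enters scale
#' differences as 21 (one step above S20), so ordering is preserved without
#' inventing a dB value.
#'
#' @export
NO_RESPONSE <- 21L

#' @rdname NO_RESPONSE
#' @param scale integer hearing-scale vector.
#' @return `is_no_response()`: logical vector.
#' @export
is_no_response <- function(scale) {
  !is.na(scale) & scale == NO_RESPONSE
}

#' Convert a hearing scale to its dB HL equivalent
#'
#' Scale k corresponds to 5k dB HL on the stratified grid (S5 = 25 dB HL,
#' S17 = 85 dB HL).
#'
#' @param scale integer vector of scale indices in 1..20.
#' @return numeric vector of levels in dB HL.
#' @examples
#' scale_to_db(5)   # 25
#' scale_to_db(17)  # 85
#' @export
scale_to_db <- function(scale) {
  scale <- as.integer(scale)
  if (anyNA(scale)) stop("scale must not contain NA")
  if (any(scale == NO_RESPONSE)) {
    stop("NO_RESPONSE has no dB HL equivalent")
  }
  if (any(scale < 1L | scale > 20L)) {
    stop("scale index must lie in 1..20")
  }
  5 * as.numeric(scale)
}

#' Convert a level in dB HL to the smallest covering hearing scale
#'
#' Returns the smallest index k with 5k >= level.  Levels of 5 dB HL or
#' better clamp to S1 (the screening floor); levels above 100 dB HL exceed
#' S20 and map to [NO_RESPONSE].
#'
#' @param level numeric vector, dB HL.
#' @return integer vector of scale indices (21 = `NO_RESPONSE`).
#' @export
db_to_scale <- function(level) {
  if (anyNA(level)) stop("level must not contain NA")
  out <- pmax(1L, as.integer(ceiling(level / 5)))
  out[level > 100] <- NO_RESPONSE
  out
}

#' Format hearing scales as S-labels
#'
#' @param scale integer vector (21 = `NO_RESPONSE`).
#' @return character vector like `"S17"`, with `"NR"` for no response.
#' @export
format_scale <- function(scale) {
  ifelse(is.na(scale), NA_character_,
         ifelse(scale == NO_RESPONSE, "NR", paste0("S", scale)))
}

#' Construct an audiogram
#'
#' An audiogram maps (ear, frequency) to an air-conduction threshold in
#' dB HL.  Both ears must cover the same frequency set; thresholds must lie
#' in \[-10, 120\] dB HL.
#'
#' @param left,right numeric vectors of thresholds in dB HL, one per
#'   frequency, either named by frequency or in the order of `frequencies`.
#' @param frequencies integer vector of frequencies in Hz (default the four
#'   HST frequencies).
#' @param reliable named logical, per-ear reliability flags.
#' @return an object of class `audiogram`: a 2 x nfreq threshold matrix with
#'   rows `left`, `right`.
#' @examples
#' audiogram(left = c(20, 20, 15, 10), right = c(83, 60, 55, 40))
#' @export
audiogram <- function(left, right, frequencies = HST_FREQUENCIES,
                      reliable = c(left = TRUE, right = TRUE)) {
  frequencies <- as.integer(frequencies)
  fix <- function(x, who) {
    if (!is.null(names(x))) {
      miss <- setdiff(as.character(frequencies), names(x))
      if (length(miss)) {
        stop("missing threshold for ", who, " ear at ",
             paste(miss, collapse = ", "), " Hz")
      }
      x <- x[as.character(frequencies)]
    }
    if (length(x) != length(frequencies)) {
      stop(who, " ear needs one threshold per frequency")
    }
    as.numeric(x)
  }
  th <- rbind(left = fix(left, "left"), right = fix(right, "right"))
  colnames(th) <- frequencies
  if (anyNA(th)) stop("audiogram thresholds must not be NA")
  if (any(th < -10 | th > 120)) {
    stop("audiogram thresholds must lie in [-10, 120] dB HL")
  }
  structure(th, reliable = reliable, class = c("audiogram", "matrix"))
}

#' @rdname audiogram
#' @param x an `audiogram`.
#' @param ear `"left"` or `"right"`.
#' @param freq frequency in Hz (vectorised).
#' @export
threshold_at <- function(x, ear, freq) {
  stopifnot(inherits(x, "audiogram"))
  ear <- match.arg(ear, c("left", "right"))
  key <- as.character(as.integer(freq))
  miss <- setdiff(key, colnames(x))
  if (length(miss)) {
    stop("frequency ", paste(miss, collapse = ", "), " Hz not in audiogram")
  }
  unname(x[ear, key])
}

#' @export
print.audiogram <- function(x, ...) {
  cat("Audiogram (air conduction, dB HL)\n")
  print(unclass(x)[, , drop = FALSE])
  rel <- attr(x, "reliable")
  if (!is.null(rel) && !all(rel)) {
    cat("unreliable ear(s):", paste(names(rel)[!rel], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Four-frequency pure-tone average
#'
#' Arithmetic mean of the air-conduction thresholds at 0.5, 1, 2 and 4 kHz
#' for one ear.
#'
#' @param x an [audiogram].
#' @param ear `"left"` or `"right"`.
#' @param frequencies frequencies entering the average (default the four PTA
#'   frequencies).
#' @return PTA in dB HL.
#' @export
compute_pta <- function(x, ear, frequencies = HST_FREQUENCIES) {
  mean(threshold_at(x, ear, frequencies))
}

#' Modified Siegel grade of a pure-tone average
#'
#' Five-grade severity staging used for sudden sensorineural hearing loss:
#' grade 1 PTA <= 25, grade 2 26-45, grade 3 46-75, grade 4 76-90, grade 5
#' > 90 dB HL.  Non-integer PTAs are graded by the same inequalities
#' (<= 25 is grade 1, (25, 45\] grade 2, and so on).
#'
#' @param pta numeric vector of pure-tone averages, dB HL.
#' @return integer vector of grades 1..5.
#' @export
siegel_grade <- function(pta) {
  if (anyNA(pta)) stop("pta must not contain NA")
  if (any(pta < -10 | pta > 120)) stop("pta out of the audiometric range")
  1L + (pta > 25) + (pta > 45) + (pta > 75) + (pta > 90)
}

#' Interaural differences in PTA and hearing scale
#'
#' Differences are impaired minus contralateral, matching the study
#' convention; they are negative only if the designated impaired ear is in
#' fact the better one.  `NO_RESPONSE` scales enter as 21.
#'
#' @param pta_impaired,pta_contra PTA of the impaired / contralateral ear
#'   (dB HL).
#' @param scale_impaired,scale_contra hearing scale of the impaired /
#'   contralateral ear (21 = `NO_RESPONSE`).
#' @return list with `pta_diff` (dB) and `scale_diff` (scales).
#' @examples
#' interaural_difference(85, 40, 17, 8)  # scale_diff 9 (45 dB equivalent)
#' @export
interaural_difference <- function(pta_impaired, pta_contra,
                                  scale_impaired, scale_contra) {
  scale_impaired <- as.integer(scale_impaired)
  scale_contra <- as.integer(scale_contra)
  stopifnot(all(scale_impaired >= 1L & scale_impaired <= NO_RESPONSE),
            all(scale_contra >= 1L & scale_contra <= NO_RESPONSE))
  list(pta_diff = pta_impaired - pta_contra,
       scale_diff = scale_impaired - scale_contra)
}
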