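# Shared fixtures: listeners and audiograms are always built in code.

# Audiogram with per-frequency thresholds given in (500, 1000, 2000, 4000)
# Hz order; a single number gives a flat audiogram.
flat_ag <- function(left, right = left) {
  if (length(left) == 1) left <- rep(left, 4)
  if (length(right) == 1) right <- rep(right, 4)
  audiogram(left = left, right = right)
}

det_listener <- function(left, right = left) {
  listener(flat_ag(left, right), deterministic = TRUE)
}

# Random audiogram with thresholds on a 1-dB grid in [lo, hi]; values above
# 100 dB HL exercise the no-response path.
random_audiogram <- function(lo = -10, hi = 115) {
  audiogram(left = sample(seq(lo, hi), 4, replace = TRUE),
            right = sample(seq(lo, hi), 4, replace = TRUE))
}

# Independent oracle for the deterministic Hearing Scale Test: try every
# scale and report the lowest at which all four frequencies are at or
# below the scale's level.
brute_force_hst <- function(ag, ear) {
  th <- sapply(HST_FREQUENCIES, function(f) threshold_at(ag, ear, f))
  ok <- vapply(1:20, function(k) all(5 * k >= th), TRUE)
  if (!any(ok)) NO_RESPONSE else min(which(ok))
}
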