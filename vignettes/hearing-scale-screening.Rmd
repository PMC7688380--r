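---
title: "Simulating hearing-scale screening for sudden hearing loss: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hearing-scale screening for sudden hearing loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hearscreen)
```

This vignette is the package's own account of the science it implements:
the measurement models, the defaults and why they were chosen, the
numerical conventions, and the limits of what the simulations can show.

## The measurement chain

Sudden sensorineural hearing loss (SSNHL) is operationalised here, as in
clinical practice, through the *difference between the two ears*: the
premorbid hearing of a patient presenting with a sudden loss is usually
unknown, so the contralateral ear serves as the reference.  The
gold-standard call is an interaural pure-tone-average (PTA) difference of
at least 30 dB HL on conventional audiometry; the smartphone screen calls
SSNHL when the interaural *hearing-scale* difference reaches a cutoff
(5 scales = 25 dB recommended).  The package simulates both instruments
against a common ground truth — a virtual listener — so their agreement can
be studied end to end.

### The hearing-scale grid

The screen expresses hearing level on 20 stratified scales 5 dB apart.
Two anchors are fixed by the test's definition — S5 = 25 dB HL and
S17 = 85 dB HL — which force scale k ↔ 5k dB HL, spanning 5–100 dB HL.
Thresholds better than 5 dB HL clamp to S1 (a screening floor; the test
reports the *minimum audible* scale, not an exact threshold), and an ear
that misses even S20 has no minimum audible scale: the `NO_RESPONSE`
sentinel, which enters difference arithmetic as 21 — one step above S20 —
preserving ordering without inventing a dB value for an unmeasurable ear.

### The virtual listener

Responses follow the standard psychometric model
\[
p(\text{heard} \mid L) = \gamma + (1 - \gamma - \lambda)\,
F\!\left(\frac{L - t}{s}\right),
\]
with true threshold \(t\), spread \(s\) (dB), guess rate \(\gamma\) and
lapse rate \(\lambda\); \(F\) is the standard logistic CDF.  Defaults
\(s = 3\) dB, \(\gamma = \lambda = 0.02\) are conventional pure-tone
psychoacoustics values, not estimates from any cohort — the study this
package models reports no human false-positive or lapse behaviour, so the
defaults are explicit conventions and fully configurable.  The logistic
(rather than cumulative-normal) form was chosen for its closed-form
quantiles; at matched central slope the two differ negligibly relative to
the 5-dB grid.  A *deterministic* mode (heard iff \(L \ge t\), inclusive at
equality) makes every procedure's correct answer computable in closed form
and is the basis of the oracle tests.  Each listener owns a private random
stream advanced once per presentation, so results for one listener are
independent of how many others were simulated.

### The adaptive scale search

Only the descent rule of the screening app is fully specified by its
design: the level descends one scale only when all four tones
(1, 2, 4, 0.5 kHz, fixed order) are heard.  The package adopts the minimal
completion consistent with "lowest scale at which all four tones are
heard": a symmetric single-scale *ascent* on any miss, terminating when the
lowest all-correct scale is bracketed by a recorded miss one scale below
(or S1 is fully heard).  Within a block, presentation stops at the first
miss — the all-correct requirement is already violated, and this minimises
presentations.  Re-visited scales are re-tested in full (no caching of
responses), matching a live app and preserving stochastic variability.
There is no confirmation re-test of the final boundary by default
(`confirm_repeats = 0`): screening favours speed; the option exists.  A
presentation cap (default 60) marks oscillating stochastic runs invalid
rather than guessing.  For a deterministic listener the procedure provably
returns \( \max(1, \lceil \max_f t_f / 5 \rceil) \) when the worst
threshold is ≤ 100 dB HL and `NO_RESPONSE` otherwise — the brute-force
oracle the tests check against on 1,000 random audiograms.

### The gold-standard exam

The modified Hughson-Westlake procedure is simulated with textbook
parameters, since the clinical description fixes only its name: start
30 dB HL, descend 10 dB after each response, ascend 5 dB after each miss,
threshold = lowest level with ≥ 2 responses out of up to 3 ascending
presentations (a level failing its 3-visit window starts a fresh window).
Responses at the output floor (−10 dB HL) count toward the criterion since
nothing quieter can be presented; a listener never meeting the criterion up
to 120 dB HL is returned the ceiling, flagged.  For deterministic listeners
the procedure returns the true threshold rounded *up* to the 5-dB grid —
verified over a 1-dB sweep — which bounds the exam PTA within 5 dB of
truth.  1 kHz is tested twice per ear; a gap > 10 dB flags the ear
unreliable.  The PTA uses the *first* 1 kHz run: the retest is a
reliability check, not an average (which measurement enters the PTA when
both pass is not specified anywhere; first-run is the fixed convention
here).  Unreliable ears are reported and flagged, and excluded from
analysis only if `exclude_unreliable = TRUE` — flagging without discarding
keeps the analysis set intact.

### Calibration numerics

Device calibration relates dB HL to dB SPL through reference-equivalent
threshold sound pressure levels (RETSPL); the shipped default is an
identity table, because transducer-specific constants live in external
standards documents and inventing them would be worse than requiring them
(`retspl_table()` accepts any values).  The ascending search (1-dB steps
from 10 dB below a known threshold) and the 2-down/1-up staircase with
3-reversal stopping mirror the calibration protocol.  The staircase
estimator is the mean of reversal levels — the protocol names the stopping
rule but not the estimator, and the reversal mean is standard practice
(configurable, including discarding initial reversals).  Transformed
up-down theory puts the 2-down/1-up equilibrium at the level where
\(p(\text{heard})^2 = 1/2\), i.e. the 70.7% point of the psychometric
function; with the 3-reversal protocol start-up bias dominates, so the
convergence test reads the asymptote instead: 12 reversals with the first
4 discarded, 2,000 seeded runs, agreement within 0.5 dB.  Channel and
device output checks pass strictly below 1 dB (left/right earphones) and
1.5 dB (device to device).

### Triage and referral

Per-ear scales classify subjects into ≤S5 / S6–S10 / >S10 by the worse
ear; referral for comprehensive assessment follows a worse scale above S10
or interaural asymmetry.  The workflow's narrative describes asymmetry
"greater than 5 scales" while the validity analysis evaluates a 5-scale
cutoff whose 25-dB equivalent and operating point only make sense as an
inclusive Δ ≥ 5 rule; the package adopts ≥ for both referral and diagnosis
so that every screen-positive subject at the recommended cutoff is referred
(a property the tests enforce).  The impaired ear is the one with the
higher scale, ties broken by higher exam PTA, then right — the study takes
the affected side from clinical presentation, which a simulator must
operationalise.  By default every subject receives the conventional exam
(as in a validity study, where all participants underwent both tests);
setting `exam_all = FALSE` restricts the exam to referred subjects, as the
deployed workflow would.

## Validity statistics

Sensitivity, specificity, PPV and NPV are binomial proportions; their 95%
intervals are exact Clopper-Pearson (beta-quantile) intervals.  The choice
is forced by recomputation: Wilson intervals do *not* reproduce the
published bounds (14/21 gives a 45.4% lower limit against the printed
43.0%), while the exact intervals reproduce every printed bound to 0.1%.
The correlation interval is the Fisher-z construction
\(\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})\), which reproduces the
published .82–.92 for r = .88 at n = 88.  (The companion interval printed
for r = .84, .77–.90, does not reproduce at n = 88 — Fisher-z gives
.77–.89; whether a different n or rounding path produced it is unknowable
from the printed record, so it is documented here and not asserted.)
One-way ANOVA across scale-difference groups is the classical
fixed-effects F test.

`reconstruct_counts()` inverts a printed validity row: it exhaustively
enumerates all integer 2×2 tables at the stated n and keeps those whose
four metrics reproduce the printed one-decimal percentages.  Published
tables are not rounded uniformly — one printed cell (82.3 for 14/17 =
82.35%) is a truncation while others are rounded half-up — so a computed
metric "matches" if either convention reproduces the printed value.  Under
this rule each of the three published rows at n = 88 has exactly one
solution; zero or multiple solutions are an error, never a guess.

## The synthetic cohort

The generator emulates the *post-exclusion* referral cohort of the validity
study: n = 88 adults, 50% female (exact by largest-remainder assignment),
age ~ Normal(46, 14.7²) truncated to 18–90, worst-ear Siegel-grade mixture
8/9/49/18/16% (again exact at n = 88: counts 7/8/43/16/14), and 67/88
gold-standard positives.  Per subject: a grade is drawn, a target
impaired-ear PTA uniform within that grade's interval — g1 [0, 25],
g2 (25, 45], g3 (45, 75], g4 (75, 90], g5 (90, 120] dB HL; the floor of 0
for grade 1 and ceiling of 120 for grade 5 are the generator's own bounds,
chosen as plausible for referred patients — then per-frequency thresholds =
target + loss-shape offsets (70% flat, 30% down-sloping with +10/+20 dB at
2/4 kHz, re-centred) + Normal(0, 4 dB) jitter, re-centred so the PTA is
exact (clamping deficits redistributed across unclamped frequencies).  The
contralateral ear's PTA is Normal(15, 7) truncated to [−10, 60] dB HL,
*further conditioned on the subject's stratified gold label* so that
prevalence is controlled at 67/88 without breaking the marginal; labels are
finally recomputed from the finished audiograms, so a label can never
contradict its audiogram.  Positives are assigned to the subjects with the
highest impaired PTAs, where the required interaural gap is feasible.
Bilateral- and conductive-loss flags are always `FALSE`: the emulated
cohort is post-exclusion (the workflow's exclusion logic is still
implemented and tested on hand-constructed records).  Under these defaults
the expected worst-ear PTA is ≈ 65 dB HL, close to the reported 67.1.

What the generator does **not** emulate: air-bone gaps (conductive loss),
progression over the 72-hour window, frequency-dependent psychometric
slopes, attention drift, or any correlation between age/sex and hearing.
Passing tests on this cohort therefore demonstrate the *procedures'*
correctness and the qualitative validity pattern (sensitivity falling and
specificity rising with the cutoff; scale×5 vs PTA correlation > 0.8
pooled over ears), not the study's exact cohort-specific coefficients —
the published r = .88 depends on the real cohort's threshold distribution
and is deliberately not a simulation target.

## Numerical conventions and problem sizes

* Rounding for comparison with printed percentages: half-up to 1 decimal
  (with truncation accepted in reconstruction, above).  R's `round()` is
  banker's rounding and is not used for this purpose.
* Deterministic-listener equality at threshold is "heard" (inclusive),
  making the scale-search oracle exact on grid boundaries.
* Scale arithmetic treats `NO_RESPONSE` as 21; conversion of 21 to dB is an
  error, never 105 dB.
* Seeds: every stochastic entry point takes one; listeners draw their
  private seeds from the ambient stream when not given one, so a single
  `set.seed()` (or the CLI `--seed`) reproduces an entire pipeline, and
  cohort generation and listener streams never perturb the caller's RNG.
* Test problem sizes were chosen to make Monte-Carlo error small relative
  to the asserted tolerances while keeping the suite fast: 1,000 random
  audiograms for the scale-search oracle, a 1-dB sweep across the full
  audiometric range for the exam, 2,000 staircase runs (±0.5 dB), 5,000
  replicates for interval coverage, and a 2,000-subject cohort for the
  end-to-end pattern checks.

## Known limitations

The ascent rule of the scale search and the exact Hughson-Westlake
parameters are stated assumptions where the source procedures are silent;
both are configurable, and the package's results should be read as
conditional on them.  Simulated time (tone durations, inter-stimulus
intervals) is logged metadata only.  The screen's single joint scale for
all four frequencies is assumed (per its "all four tones" rule) rather than
per-frequency scales.  Predictive values inherit the synthetic cohort's
67/88 prevalence, which mirrors a tertiary referral population — not a
general screening population.
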