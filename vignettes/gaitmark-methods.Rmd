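---
title: "Insole gait markers: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insole gait markers: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmark)
```

## The problem

Parkinsonian gait differs from healthy gait in two families of measurements.
*Kinematic* markers describe the geometry and timing of the movement: gait
speed, swing/stance/double-support durations and — crucially — their
stride-to-stride variability, which is elevated in Parkinson's disease.
*Dynamic* markers describe the forces: here, summaries of the vertical
ground reaction force (VGRF) recorded by force-sensitive insoles with eight
pressure sensors under each foot. `gaitmark` implements both analyses on a
common segmentation backbone and compares PD-like and healthy-like (HS)
groups variable by variable. The scientific expectation is the
*force/rhythm dichotomy*: timing dispersion separates the groups while
whole-trial force summaries do not.

## Segmentation model

Per-foot total force is the sum of the eight sensor channels. The
differential GRF, δ = R_tot − L_tot, is computed and exposed as the QC
trace, but phase labelling itself uses the two per-foot contact series: δ
alone cannot distinguish double support (both feet loaded, δ ≈ 0) from an
airborne artifact (neither loaded, δ = 0). This is a deliberate,
well-defined reading of the δ-based segmentation idea.

* **Contact** = total force above a threshold, then *debounced*: runs of
  either state shorter than `min_phase_duration` (default 50 ms ≈ 5 samples
  at 100 Hz) are merged into their neighbours, shortest first; trial-edge
  runs are never flipped. The default threshold is 20 N for
  newton-calibrated data and 3% of the per-subject maximum total force for
  uncalibrated/percent data; `"auto"` estimates the no-load baseline from
  the lowest-35% samples and sets the threshold 8 baseline-SDs above it,
  which is what noisy hardware needs (a truncated-at-zero noise floor on 16
  channels biases the swing-phase total upward). Thresholds are recorded in
  the `contact_series` object.
* **Phases** follow the per-sample truth table: both feet = DLS, left only =
  SLS-L, right only = SLS-R, neither = airborne.
* **Cycles** are anchored "from the first double limb support to the end of
  the subsequent left single limb support": a cycle starts at the onset of a
  DLS run immediately followed by SLS-R (i.e. at a right-foot initial
  contact) and ends at the onset of the next DLS. Indices are 1-based with
  half-open `[start, end)` extents; durations are `(end − start) / fs`.
  Cycles whose interior is not exactly DLS → SLS-R → DLS → SLS-L are kept in
  the segmentation table but marked invalid (`"airborne gap"` or
  `"irregular phase pattern"`) instead of erroring the trial; leading and
  trailing fragments are dropped.
* **Outlier rule**: cycles with SL > S̄L + 2·SD(SL) are discarded, with the
  mean and SD computed once over all segmented cycles (not iteratively) and
  the rule applied strictly one-sided (upper tail only), exactly as the
  procedure is usually stated; shortened cycles always survive. Whether the
  reference procedure recomputed the statistics after rejection is unstated;
  we do not.

## Features

Ten per-cycle parameters (left/right stance and swing, seconds and % of
stride; double support, seconds and %) are summarised per subject by
average, median, SD and IQR over the accepted cycles: 40 kinematic
variables, plus gait speed (m/s) and Timed-Up-and-Go (s) copied from
metadata — insoles carry no spatial information, so these two covariates are
dataset-provided and get no dispersion indices. Dynamic features are the
mean/median/SD/IQR of each foot's total force over *all* trial samples
(swing-phase near-zeros included): 8 variables, for 50 in total — the
Bonferroni correction factor.

Conventions: SD is the sample (n−1) standard deviation; median and IQR use
linear-interpolation quantiles (R type 7), configurable via `quantile_type`
because quantile conventions differ between packages. Uncalibrated volt
recordings must be normalized (`normalize_voltage`) to percent of the
device's maximal output before dynamic analysis, and the suite refuses to
mix units implicitly.

## Statistics

Group comparisons use the pooled-variance Student t (not Welch): the
reported degrees of freedom in this literature are n₁ + n₂ − 2 (194 for
88 + 108, 150 for 62 + 90), which is diagnostic of the pooled form. The sign
convention is HS − PD. Significance is declared at α/m = 0.05/50 = 0.001,
with m fixed at 50 (the full planned variable set) regardless of how many
variables are actually present — configurable. ROC analysis is gated on the
corrected t-test: only significant kinematic markers get an AUC. AUC is the
Mann–Whitney probability that a PD value exceeds an HS value (midranks for
ties), PD is the positive class, and no orientation flipping is applied — a
marker that decreases in PD (gait speed) is reported with AUC < 0.5. The SE
is Hanley–McNeil (DeLong available via `method = "delong"`), the 95% CI is
the normal approximation clipped to [0, 1], and p tests AUC against 0.5.

A reference table of published group summaries for the same 50-variable
layout ships in `inst/extdata/` (`reference_group_summary()`); the test
suite recomputes every printed t from the printed means/SDs/Ns. Exact
agreement to ±0.02 is *not* attainable for all rows: the printed t values
were computed from unrounded data, and for variables whose means are of
order 0.01 the 3-decimal rounding of the printed inputs alone moves t by up
to ≈0.4. The suite therefore also checks the sharper, well-posed property
that every printed t lies inside the interval reachable by perturbing the
printed summaries by half a printing ulp (±0.0005) — which holds for all 50
rows — and that the recomputed p-values reproduce the printed significance
stars exactly.

## The synthetic cohort generator

The simulator emulates what the public insole gait datasets provide:
level-ground walking trials of one to five minutes at ~100 Hz, two feet ×
8 sensors + totals, group contrasts in gait speed, TUG, and timing
variability, and an uncalibrated-voltage recording mode.

**Cycle timing.** Stride times are Gaussian with mean ~1.06 s (HS) / 1.076 s
(PD) and CV 3% / 4.4%. The four phase fractions are drawn per cycle — two
swing fractions from N(1 − stance, stance_fraction_sd), two DLS episodes
from N(dls, dls_sd) — and the DLS episodes absorb the closure residual
equally so the phases tile the stride *exactly*. This choice puts the
programmed SD on the swing/stance fractions (the quantities the dispersion
markers measure) at the cost of some extra variance on the DLS episodes.
Consistency of the tiling forces stance = 0.5 + dls for symmetric gait, so a
subject-level stance shift moves the DLS mean with it.

**Force.** During stance the total force follows a piecewise raised-cosine
"M" curve: a fast loading transient (1.5% of stance) to 0.55 body weight
(BW), peaks of 1.15 BW at 25% and 75% of stance, a mid-stance valley of
0.75 BW, and a symmetric unloading transient. No waveform is canonical in
the source material; any smooth two-peak curve qualifies, and all knots are
arguments of `stance_waveform()`. The force is spread over the 8 sensors by
heel-to-toe Gaussian activation windows (renormalized so sensors sum to the
total); the insole geometry is decorative, not semantic. Sensor noise is
additive Gaussian truncated at zero (default SD 2 N per channel, typical of
resistive insole baselines), and totals are re-summed after noise. A
quarter-sample evaluation floor makes the sampled force strictly positive on
every in-contact sample, so ground-truth contact intervals and the sampled
signal agree at the sample level.

**Between-subject heterogeneity.** Each subject draws personal values of the
stride-time mean, stride CV, stance fraction and the within-subject SDs from
Gaussians around the profile means (`*_between_sd` fields). This layer is
essential: without it all subjects of a group are statistically identical,
every programmed mean contrast — including the ~1 percentage-point stance%
shift — becomes significant at n = 88/108, and the null side of the
force/rhythm dichotomy cannot exist. Defaults for the personal *means*
(stance% between-SD 3.1/4.0, stride-time between-SD 0.10/0.13 s) follow the
published between-subject SD columns. Defaults for the heterogeneity of the
*variability* parameters are set to ~30% CV of the parameter rather than to
the published SD columns of the dispersion features, because those printed
SDs pool four cohorts with different protocols and contain heavy-tailed
outliers (e.g. a PD SD-stance spread 10× the HS one) that a homogeneous
single-protocol generator should not, and 30% is in line with reported
test–retest spreads of gait-variability indices. Body weight varies
700 ± 120 N identically in both groups; force parameters carry *no* group
contrast, making the dynamic null exact by construction.

**Covariates.** Gait speed and TUG are drawn from the profile Gaussians as
metadata, not derived from the force signal — mirroring how the real
datasets provide them. Age is metadata only; no age effect is modelled.

**Seeds.** `simulate_cohort` derives per-subject seeds by a counter-based
rule (`subject_seed`), so a subject's data depends only on the master seed
and its index; the pipeline streams subjects one at a time and reproduces
the cohort bit-identically.

**What a green test does not establish.** The generator produces idealized
walking: no turns, no freezing-of-gait or tremor artifacts, no
mediolateral/anteroposterior force components, no drift or sensor failure,
Gaussian phase jitter rather than the long-range-correlated stride dynamics
of real gait, and clinical covariates independent of the force signal.
Recovery of programmed parameters therefore validates the pipeline's
*correctness*, not its robustness to everything real hardware produces.

## Numerical choices and degenerate inputs

* Boundary indices: sample *i* is at time (i−1)/fs; an event at time t maps
  to the first sample with time ≥ t. Detection recovers boundaries within 1
  sample on noise-free signals and 2 samples at 2%-BW noise (with the
  noise-aware threshold), which biases stance short by ≲ 3 ms per side —
  within the 0.5 percentage-point recovery tolerance at 100 Hz.
* Zero pooled variance: equal means give t = 0, p = 1; unequal means are an
  error rather than ±Inf.
* Perfect ROC separation gives SE = 0 and p = 0 (p = 1 only if AUC = 0.5).
* Totals present in a file that disagree with sensor sums by > 1% warn and
  the *file* totals win (they are what the δ-based analysis would have
  used); absent totals are recomputed from the sensors.
* With a single segmented cycle the outlier rule passes it through; with
  < 2 accepted cycles dispersion features are NA; with 0 the subject is
  excluded with a logged reason.
* 50 ms debouncing suppresses heel-strike chatter; it cannot create or
  destroy phases longer than 50 ms.

## Desk-scale test budget

The simulation-based acceptance checks run cohorts of 88 + 108 subjects at
60 s per trial (~55 cycles/subject) over 20 master seeds — about 3 minutes
on one CPU. Sixty seconds is the lower end of the protocols the real
datasets use (80 s–5 min) and is enough for stable dispersion indices; the
null-calibration and property tests use smaller cohorts and shorter trials,
scaled down from their nominal statements to keep the suite fast while
preserving the asserted property.

## Known limitations

Gait speed and TUG cannot be validated against the force signal (they are
independent metadata). The DLS% level implied by stance% (2·stance − 100)
need not match published DLS% columns, which appear to use a different DLS
convention in one source cohort; directions and dispersion behaviour are
unaffected. The CLI writes ground-truth sidecars as JSON; there is no WFDB
binary support and no dataset download client.
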