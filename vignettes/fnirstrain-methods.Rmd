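---
title: "Methods: in-session fNIRS analysis of emotion-regulation training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-session fNIRS analysis of emotion-regulation training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirstrain)
```

## The analysis problem

`fnirstrain` implements the in-session analysis of a block-design fNIRS
experiment: patients practice guided emotion-regulation strategies in
eight therapy sessions, each consisting of twenty 40-s training trials
alternating (block-randomized per ten trials, five of each) with twenty
40-s rest trials, while cortical oxygenation is recorded at 10 Hz with a
continuous-wave two-wavelength (695/830 nm) optode montage over
bilateral prefrontal cortex and a parietal patch. The scientific
quantities are (i) the training-minus-control contrast of corrected
oxygenated hemoglobin (O2Hb) per subject, session, session third and
region of interest (ROI), (ii) its evolution over sessions and session
phases, and (iii) the coupling of per-trial subjective ratings (burden,
self-compassion, equanimity, effort) to that oxygenation.

Because the clinical recordings are not public, the package pairs every
analysis stage with a synthetic-cohort generator whose ground truth is
known, so each stage can be validated by parameter recovery rather than
by reference outputs.

## From light to concentration

Raw intensities are converted to optical density changes,
`dOD(t) = -ln(I(t)/I0)` (natural log; `I0` is the mean over a baseline
window, default the first 30 s), then to chromophore concentration
changes by inverting the modified Beer-Lambert system per channel:
`dOD_lambda = d * DPF_lambda * sum_c eps(lambda, c) * dC_c`. The
extinction coefficients are not part of this study's contribution and
are taken from the standard hemoglobin-spectrum compendium interpolated
at 695/830 nm (O2Hb 0.283 / 0.974, HHb 1.923 / 0.693, in 1/(mM cm));
the differential pathlength factor defaults to 6.0 at both wavelengths
and the source-detector distance to 3 cm. All three are configurable and
recorded in the series provenance: the final z-transform makes results
invariant to the overall positive scale of these constants but not to
the relative mixing, so reproducibility requires knowing them.

The simulator's forward model uses a double-gamma hemodynamic response
(gamma shapes `peak_delay + 1` and `undershoot_delay + 1`, rate 1,
defaults peaking at 6 s with a 16-s undershoot, peak normalized to 1)
convolved with the training-trial boxcar; the convolution kernel is
normalized to unit DC gain so a sustained unit block plateaus at 1.

## The cleaning chain

Stages run in this order, mirroring the acquisition pipeline:

1. **Bad-channel detection and interpolation.** A channel is flagged if
   its variance falls outside `[0.01, 100]` times the median channel
   variance in any band, or if more than 75 % of its samples equal their
   predecessor (a channel stuck for most of the recording). These
   automated rules replace manual visual inspection for the sake of
   reproducibility. Flagged channels are replaced by the
   Gaussian-distance-weighted (`sigma` = 30 mm) average of good channels
   in the same probeset; a channel with no good probeset neighbor stays
   flagged and is dropped from its ROI average with a warning.
2. **Temporal Derivative Distribution Repair (TDDR).** The signal is
   split at 0.5 Hz; on the low-frequency part the temporal derivative is
   iteratively re-weighted with Tukey biweights
   (`w = (1 - r'^2)^2` for `|r'| < 1`, `r' = residual /
   (4.685 * 1.4826 * MAD)`) around a robust location until the location
   changes by less than 1e-8; the corrected derivative
   `w * (derivative - location)` is re-integrated, the initial value
   restored, and the high-frequency part added back. Two numerical
   guards matter in practice. First, when the robust scale collapses
   relative to the derivative's spread (below 1e-6 of its sd, as happens
   for exactly noise-free piecewise-constant signals), the majority of
   true hemodynamic transitions would be rejected as outliers; the
   signal is then returned unrepaired and flagged `degenerate`. Second,
   because inlier weights are slightly below 1, re-integration
   accumulates a slow wander and pins the recording's net displacement
   to zero; both effects live almost entirely below the analysis band
   and are removed by the subsequent band-pass, which is why this
   package always evaluates TDDR fidelity within that band. TDDR's
   target artifact class is abrupt persistent baseline shifts; brief
   transient glitches mostly live above the 0.5 Hz split and pass
   through, which is the documented behavior of the algorithm rather
   than a defect.
3. **Correlation-based signal improvement (CBSI).** With
   `alpha = sd(O2Hb)/sd(HHb)` on mean-centered series, the corrected
   signal is `x0 = (O2Hb - alpha * HHb)/2` and the corrected HHb is
   `-x0/alpha` (correlation exactly -1 by construction). Only the
   corrected O2Hb is analyzed further.
4. **Band-pass 0.01-0.1 Hz.** Third-order Butterworth applied
   forward-backward (zero phase — required because event-related
   averages are phase-sensitive). The filter is applied over an
   odd-reflection extension of about `5 / low_edge` seconds at each end:
   without that padding the edge transient of a 0.01 Hz high-pass lasts
   minutes and leaks DC (we measured a DC gain of 0.47 with naive
   forward-backward filtering, versus ~1e-7 with padding).
5. **Second interpolation pass** with the same rules, catching channels
   destabilized by the corrections.
6. **Global-signal reduction.** Each channel's global component is the
   Gaussian-kernel-weighted (`sigma` = 40, interpreted as millimetres of
   scalp distance) average of the *other* channels, row-normalized to
   sum to 1, and is subtracted. The kernel excludes the channel itself:
   a leave-one-out spatial prediction removes a shared additive
   component exactly (weights sum to one) while leaving a signal
   localized to a single, spatially isolated channel untouched;
   including the channel would make the "global" estimate mostly the
   channel itself and subtract genuine local activation.
7. **z-transform** per channel per session (sample sd, n-1), making
   sessions comparable across subjects.

## Trials, thirds, ROIs, contrasts

Event-related trial scores subtract the mean of a pre-onset baseline
(default -5-0 s) and average the analysis window (default 5-40 s
post-onset, skipping the hemodynamic rise); windows are half-open
`[start, end)` so the onset sample belongs to the trial, never the
baseline. Within each condition, trials are partitioned *by trial
order* (not wall-clock time) into three contiguous session thirds,
remainders going to earlier thirds (20 trials per condition gives
7/7/6). Channel scores are averaged without weighting into five ROIs —
lIFG {6,7,9}, lDLPFC {10,11,12}, rIFG {18,19,21}, rDLPFC {20,23,24},
SAC {25,26,27,28,30,31,32,35,36} — and the condition contrast is
`mean(training) - mean(control)` per subject x session x phase x ROI.
Channel-level contrasts across subjects also yield one-sample Cohen's d
activation maps (`d = mean/sd`; cells with zero between-subject sd are
flagged missing).

## The statistical layer

**Repeated-measures MANOVA.** Per-subject cell means are transformed by
the Kronecker product of orthonormal polynomial contrasts (for factors
in the effect) and normalized averaging vectors (for the rest). The
transformed rows are pooled as multivariate observations over the
dependent variables: `H` collects hypothesis cross-products (`n` times
the outer products of row means, or group deviations for
between-factor effects), `E` the within-cell error cross-products with
`q * (n - g)` degrees of freedom, and Wilks
`lambda = det(E) / det(E + H)` is converted to F by Rao's
approximation; multivariate partial eta squared is
`1 - lambda^(1/s)`. This is the convention of mainstream GLM
repeated-measures software, which we confirmed by reproducing its
degrees of freedom exactly on this design (e.g. F(4, 38) for the
constant term over four DVs at n = 42, F(35, 1192.9) for an
eight-level within effect over five DVs). With difference scores as
input, the "constant" effect is the main effect of the condition
contrast. With one DV and two levels the machinery collapses exactly to
the paired t-test (F = t^2), which the tests assert to 1e-8.

**Univariate follow-ups** per DV use Huynh-Feldt-corrected degrees of
freedom: Greenhouse-Geisser epsilon from the orthonormalized contrast
covariance, then the Huynh-Feldt adjustment
`(n q e - 2) / (q (n - 1 - q e))` capped at 1 (with `n` replaced by
`n - g + 1` under a between factor); with two levels epsilon is exactly
1. Partial eta squared is `SS_effect / (SS_effect + SS_error)`.

**Polynomial contrasts** (linear, quadratic, cubic) are one-sample — or
group-difference — F tests on orthonormal contrast scores; orders above
cubic are computed but flagged unreported, treating higher orders as
spurious fluctuation. For multi-scale data the per-DV contrast rows are
the interpretable ones; the pooled cross-DV row mixes units and
directions and is retained only for completeness.

**Multiplicity.** Benjamini-Hochberg step-up adjustment
(`stats::p.adjust`), with the family defined per call: the twelve
questionnaire post-hoc comparisons form one family; ROI follow-ups form
one family per rmMANOVA effect. Chi-squared tests (goodness-of-fit
against uniform or given shares, independence for tables) are computed
without continuity correction so they match hand-computed
`sum((O-E)^2/E)` values.

**Lagged mixed models.** For one rating and one ROI, training-trial
records are modeled as `rating ~ session + phase + session:phase +
rating_lagged + WP + BP + session:WP + phase:WP + session:BP + phase:BP
+ (1 | subject)` by REML with Satterthwaite degrees of freedom
(lmerTest). Session (1-8) and phase (1-3) enter as numeric covariates,
matching a reporting style of single slopes per term; the oxygenation
predictor is split by person-mean centering into a within-person
deviation (WP, summing to zero within subject) and the between-person
subject mean (BP, grand-mean centered by default, configurable). The
lag is computed within subject x session — trials are session-bound, so
no lag crosses a session boundary — and first trials per session are
dropped. The three-way `session:phase:WP/BP` terms are available behind
`include_threeway = TRUE` but are off by default: the two-way set is
the interpretable reading of the interaction structure. Marginal R^2 is
`var(X beta) / (var(X beta) + tau^2 + sigma^2)`. Satterthwaite comes
from lmerTest's implementation (gradient of the variance of estimable
functions with respect to the variance components); no fallback
approximation is needed in this environment.

## The synthetic cohort

The generator reproduces the statistical structure the analysis
assumes, with every injected effect stored as ground truth:

* **Design**: 42 subjects x 8 sessions; per session 40 trials
  block-randomized per 10 (5 training + 5 control), 40-s trials,
  inter-trial talk gaps uniform on 20-60 s (the study reports sessions
  of roughly 1-1.5 h, which this range respects); 10 Hz sampling.
* **Signals** (concentration units, pre-z): per channel, the ROI
  amplitude (prefrontal 0.8-1.0, SAC 0.3, 0.15 background outside named
  ROIs so no channel is silent, declining by 0.06/session in bilateral
  DLPFC) times the HRF-convolved training boxcar; cardiac (1.1 Hz),
  respiratory (0.25 Hz) and Mayer-wave (0.1 Hz) sinusoids with random
  phases; a normalized random-walk drift; Poisson motion artifacts
  (persistent baseline steps, 0.5/min, amplitude 2 — the artifact class
  TDDR repairs); a shared smoothed global component (sd 0.5); white
  noise (sd 0.3). HHb is `-O2Hb/3` plus independent noise so CBSI sees
  realistic anti-correlated structure; the ratio is configurable.
* **Contrast-level cohorts** draw the subject x session x phase x ROI
  records directly: cell means 0.30-0.35 z in prefrontal ROIs with a
  -0.035/session DLPFC slope, subject intercepts split into a shared
  and an ROI-specific component (0.25 each; a single shared intercept
  would make the ROI covariance near-singular and inflate multivariate
  effect sizes), residual sd 0.45. These defaults were calibrated once
  so the constant-term effect sizes land in the 0.2-0.5 partial-eta-
  squared band at n = 42 — calibration targets, not truth claims.
* **Ratings**: bounded 0-10 continuous scale (the study does not print
  its scale's range; this is a stand-in), linear session and phase
  trends per condition (burden and effort decline, self-compassion and
  equanimity rise; effort carries a quadratic phase component), a
  per-subject deviation of the training-control gap (sd 1.5 — the
  source of between-subject contrast variance; without it the contrast
  ηp² saturates near 1), session-level subject intercepts, trial noise.
* **Interventions**: events draw session, phase and category
  independently from the observed shares — sessions declining
  14 % -> 11.4 %, phases 39.2/42.4/18.3 %, and thirteen category labels
  (cognitive perspective change split into reframing 22.2 %,
  self-compassion 13.4 %, acceptance 10.6 %; validation 15.6 %;
  distancing 14.4 %; attention regulation 13.6 %; seven minor categories
  sharing the rest in descending order).
* **Questionnaires**: two-group cross-over over three timepoints —
  treatment-first improves t1->t2 then holds, TAU-first improves
  t2->t3 — with each scale's total change set to
  `d13 * sqrt(2) * occasion_sd` so the paired t1->t3 effect size
  targets the configured values (BDI -1.47 from a 26.51 (SD 7.78)
  baseline, SWE 0.88, SCS 1.75, SRQ -1.85). Scales are generated
  independently given the subject; real questionnaire batteries
  correlate across scales, which the multivariate tests here therefore
  do not exercise.
* **Mixed-model cohorts** generate training-trial ratings from exactly
  the lagged-model process (defaults: lag 0.3, WP -0.4, BP +0.4 —
  opposite signs, mirroring the observed dissociation between momentary
  and habitual oxygenation levels — random-intercept sd 0.8, residual
  0.8).

Sub-seeds for every subject/session/generator are derived
deterministically from one master seed (kept below 2^31), so a bundle
is bit-reproducible.

**What passing tests do and do not show.** The generator matches the
study's design constants and headline effect sizes, but its noise is
stationary and Gaussian, its physiology is three fixed sinusoids, its
motion model is idealized steps, scalp geometry is nominal, and ratings
are continuous rather than ordinal. Recovery of injected effects
demonstrates that the pipeline is correct and calibrated under these
assumptions; it does not certify performance on real recordings with
non-stationary physiology, optode drift, or floor/ceiling effects in
ratings.

## Problem sizes in the tests and acceptance runs

Signal-level checks run single sessions (10-40 trials, ~800-3400 s at
10 Hz, 36 channels); statistical checks use the default 42-subject
contrast-level cohort; type-I simulations use 1000 replicates at a
reduced 20 subjects; questionnaire effect-size recovery averages 200
replicates; TDDR efficacy uses 20 spike-injected sessions. These sizes
were chosen to make every run reproducible at a desk while keeping
Monte-Carlo error well inside the asserted bounds.

## Known limitations

* Only the TSV interchange format is supported for channel time series;
  there is no HDF5/SNIRF reader in this build.
* The multivariate layer assumes complete balanced within-cells per
  subject; sessions lost to bad data should be excluded listwise (or
  flagged upstream) — there is no imputation.
* The doubly-multivariate convention treats transformed contrast rows
  as exchangeable observations; its null calibration is exact for the
  constant term (verified by simulation) and approximate for
  higher-order effects.
* Huynh-Feldt under a between factor uses the single-group formula with
  `n - g + 1`, a standard but not unique choice.
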