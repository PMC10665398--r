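---
title: "Vascular stiffness thresholds and blood-pressure response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular stiffness thresholds and blood-pressure response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiffwave)
```

## The problem

Opioid sensitivity varies between patients, and the strength of the
sympathetic (blood-pressure) response to a standard noxious stimulus —
surgical skin incision — is hard to predict from conventional monitors,
which track within-patient change rather than between-patient sensitivity.
One proposed individual index is the *minimum evoked current of the
vascular stiffness value* (MEC_K): the weakest tetanic stimulation current
that still evokes a detectable rise in vascular stiffness under a fixed
opioid level. A lower MEC_K means a more reactive patient, and MEC_K
correlates negatively with the rate of change of systolic blood pressure
(ROC_BP) at incision.

`stiffwave` implements the full computational chain of such a study —
per-beat stiffness estimation, threshold detection, incision response, and
cohort-level validation — together with synthetic-data generators carrying
known ground truth, so every stage is testable without patient data.

## The spring-damper beat model

The arterial wall is modelled as a mechanical impedance: a spring
(stiffness K, mmHg per % PPG) in parallel with a damper (viscosity B,
mmHg·s per % PPG). Writing Pb(t) for arterial pressure, Pl(t) for PPG
amplitude (a proxy for wall displacement, in percent of full scale), and
t0 for the beat onset, within-beat changes obey

$$\mathrm{dPb}(t) = K\,\mathrm{dPl}(t) + B\,\mathrm{d\dot Pl}(t),$$

where each d-quantity is the difference from its value at t0. `fit_beat()`
estimates (K, B) once per heartbeat by least squares. Three numerical
choices matter:

* **No intercept.** All three difference series are exactly zero at t0 by
  construction, so the model passes through the origin and the design
  matrix has two columns only.
* **Centred R².** The coefficient of determination is computed against the
  centred total sum of squares, so the familiar 0.95 quality cut-off keeps
  its usual meaning even in a through-origin fit.
* **Derivative scheme.** The PPG derivative is a central finite difference
  at interior samples and one-sided at the edges (second-order accurate, no
  phase shift).

Beats are excluded from the K series when R² < 0.95 or when either K or B
is negative (both are physically non-negative coefficients; we read the
exclusion rule as either-negative, and record exclusion counts by reason).
Beat windows are half-open `[onset, next onset)`, with t0 the onset sample.

## MEC_K detection

Each tetanic stimulus (50 Hz, 5 s; ladder 10–80 mA in 10-mA steps) is
scored by `evaluate_stimulus()`:

* pre-stimulus K = median of valid beats in the 10 s before onset
  (`[onset − 10, onset)`; the median of an even count is the mean of the
  two middle values);
* post-stimulus K = maximum in the 20 s after the stimulus *offset*
  (`(offset, offset + 20]`). We anchor the post window at the end of the
  5-s train because "after stimulation" most naturally means after it
  ends; an onset-anchored variant is available (`anchor = "onset"`).
* a stimulus *responds* when the relative rise reaches 5%.

`detect_meck()` then applies noise rejection. The verbal rule — a ≥ 5%
rise followed by a < 5% rise at the next intensity is noise, and a silent
80-mA stimulus means "out of measurement range" — is unified here as the
**suffix rule**: MEC_K is the smallest intensity from which *every* tested
intensity upward responded. This reproduces the canonical worked example
(isolated rise at 20 mA rejected, silent 30/40 mA, sustained responses
from 50 mA: MEC_K = 50 mA), makes out-of-range exactly the empty-suffix
case, and encodes the physiological premise that true responses are
monotone in intensity. The literal pairwise reading is implemented as
`rule = "pairwise"`; the two differ only on non-monotone patterns such as
Y,Y,N,Y, which the suffix rule resolves conservatively (upward).

## ROC_BP

`compute_rocbp()` takes the median systolic BP of the last 10 beats before
incision and the maximum over a post-incision window, and reports the
*percent change* `(post/pre − 1) × 100`. The percent-change reading (rather
than the raw ratio) is forced by the magnitudes the method works with:
typical values near 18% and regression intercepts near 29% are impossible
for a ratio near 1.18. The raw ratio is returned alongside. The
post-incision window length is not part of the clinical definition; we
default to 120 s — long enough to capture the pressor peak, short enough
to end before any analgesic intervention — and expose it as a parameter.

## Cohort statistics

`run_cohort_analysis()` excludes out-of-range subjects (mirroring a
29-of-30 analysis set), then computes:

* Pearson correlation of MEC_K and ROC_BP with a two-sided t test
  (`stats::cor.test`);
* the least-squares line ROC_BP = slope·MEC_K + intercept;
* iterative two-sided Smirnov–Grubbs screening of the predicted − measured
  residuals at α = 0.05, using the Student-t critical value
  `G = ((n−1)/√n)·√(t²/(n−2+t²))`, t the upper α/(2n) quantile on n−2 df.
  Spreads at machine precision (exact fits) are treated as zero rather
  than screened — a scale-invariant statistic cannot distinguish round-off
  from data;
* with an external prediction line (e.g. from a study under a different
  anesthetic), a Bland–Altman analysis of externally predicted vs measured
  ROC_BP. *Precision* is reported as 1.96·SD of the differences — the
  half-width of the limits of agreement — which is the definition
  consistent with how such ranges are quoted;
* with two patient groups, an ANCOVA parallel-lines test: a two-sided t
  test of the slope-by-group interaction, then, under a common slope, of
  the group intercept shift — in that order, matching standard reporting.

### Sample-size planning

`required_sample_size()` returns the smallest n for which the F test of
the regression slope (df 1 and n−2, noncentrality λ = n·f² with
f² = R²/(1−R²)) reaches the target power. At R² = 0.25, α = 0.05 and power
0.8 this gives 26 cases. This is the *fixed-model* regression formulation;
it is the one whose answer matches standard planning software for this
design, and it is what the Monte-Carlo verification in the test suite
simulates — a fixed predictor with slope chosen so the noncentrality is
n·f². A random-predictor (bivariate-normal) simulation is *not* the same
quantity: its power at the fixed-model n is a few points lower, which is a
known difference between the fixed and random formulations, not an error
in either. An approximate Fisher-z mode for the random-predictor view is
provided (`method = "fisher_z"`) but is not used by default.

## What the synthetic generators emulate

* `gen_beat_waveform()` — a raised-cosine single-hump PPG pulse per beat
  (smooth, analytically differentiable, zero value and slope at beat
  boundaries) with pressure built forward from the impedance model plus
  i.i.d. Gaussian noise. The forward model uses the same discrete
  derivative operator as the estimator, so the noise-free inverse is exact
  to numerical round-off — by design, this isolates estimator correctness
  from discretisation error. Defaults: 100 Hz, 60 bpm, K = 5 mmHg/%,
  B = 0.5 mmHg·s/%, pulse 8%, baseline 80 mmHg, noise SD 0.5 mmHg.
* `gen_session()` — a per-beat K series (1 beat/s) spanning a 10–80 mA
  ladder; at/above-threshold stimuli multiply baseline K by a transient
  with linear rise (10 s to peak, within the 20-s window) and exponential
  decay (τ = 5 s), gain 0.08 + 0.002·(i − threshold) ≥ the 5% criterion;
  baseline K fluctuates with CV 1% so baseline noise alone can never cross
  5% (the CV is a modelling choice — between-stimulus K variability is not
  a measured quantity); an isolated artifactual spike can be injected at
  one sub-threshold intensity to exercise noise rejection. The default
  60-s gap guarantees return to baseline before the next pre-window, and
  a too-short gap is a configuration error.
* `gen_cohort()` — subjects drawn from a MEC_K distribution with mode
  30 mA, 60% of mass on 20–40 mA and 5% out-of-range, with
  ROC_BP = −0.27·MEC_K + 28.81 + Normal(0, 5²) %. Out-of-range subjects
  get a measured ROC_BP near the 80-mA prediction (they are weak
  responders) but never enter any MEC_K pairing. Optional two-group
  assignment with per-group slope/intercept overrides supports the
  parallel-lines analyses.
* `gen_incision_series()` — constant pre-incision systolic BP plus a
  linear post-incision ramp to a peak of `pre × (1 + rise)`, so the
  noise-free ROC_BP is exact.

What these generators do **not** emulate: real PPG morphology and motion
artifacts, respiratory and autoregulatory K drift, heart-rate variability,
non-Gaussian residuals, and any pharmacokinetics. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under the
stated model, not clinical performance on monitor data.

## Validation suite and problem sizes

The test suite checks, among others: exact noise-free (K, B) recovery over
a grid spanning [0.1, 100] × [0.01, 10]; unbiasedness over 1,000 noisy
beats (3 Monte-Carlo SE); equivalence of `detect_meck()` with an
exhaustive suffix-scan oracle on all 256 response patterns; threshold
recovery on ≥ 99% of 500 seeded sessions; Grubbs type-I error at n = 29
over 10,000 null samples (±3 binomial SE); uniformity of parallel-lines
p-values under a shared-line null over 5,000 replicates
(Kolmogorov–Smirnov at 1%); Monte-Carlo power at the returned sample size
and at n − 1 over 50,000 replicates; 95% slope-CI coverage over 1,000
cohorts of 30; and slope recovery with zero outliers in ≥ 90% of 50
thirty-subject cohorts. These sizes were chosen so each statistical check
has enough replicates for its stated tolerance while the whole suite runs
in well under a minute of simulation-heavy work per block.

## Limitations

* Beat onsets are inputs: there is no beat detector, and no PPG artifact
  rejection beyond the R²/sign filter.
* The exclusion rule is read as either-coefficient-negative; the
  both-negative reading is configurable only through the filter's inputs,
  and the clinical fiducial and sampling rate behind the per-beat fit are
  not specified by the method's description.
* The suffix rule is one consistent unification of the verbal noise rule;
  on non-monotone patterns the pairwise alternative gives smaller
  thresholds, and neither can be validated against real sessions here.
* Headline clinical coefficients (r = −0.735 and the fitted line of an
  actual cohort) depend on undeposited patient data; the package
  demonstrates parameter recovery on synthetic cohorts instead.
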