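---
title: "Detecting and quantifying radiopharmaceutical extravasation from dose-rate curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying radiopharmaceutical extravasation from dose-rate curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radextra)
library(dplyr)
```

## The problem

During an intravenous radiopharmaceutical administration, part of the injected
activity can leak into the soft tissue around the IV access instead of
entering the bloodstream (an *extravasation*). Undetected, it distorts
quantitative PET measures — the Standardized Uptake Value (SUV) is computed
with the nominal injected activity in its denominator, so any activity that
never circulated biases the SUV downward — and in radioligand therapy it can
deliver several gray of unintended local dose.

A cheap and practical way to catch these events is to strap a wearable gamma
detector near the injection site and a second one on the contralateral arm,
and record the ambient dose equivalent rate H\*(10) at 1 Hz during the
administration. In a normal administration the injection-arm signal spikes as
the bolus passes the sensor and then decays onto a plateau that converges with
the contralateral-arm signal as the activity perfuses the body. In an
extravasation the two arms never converge: a depot of activity persists under
the injection-arm sensor.

`radextra` implements this monitoring method end to end: curve I/O and
pairing, anchoring/windowing/selective smoothing, plateau detection, the
metric vector, threshold classification, residual-activity and self-dose
quantification, the SUV correction coefficient and its cohort calibration,
plus a simulator that generates two-arm curves with known ground truth.

## The processing chain and its parameters

**Anchoring and windowing.** All analysis is anchored at the injection-curve
global maximum `DR_in_max` (the bolus transit), found on the *raw* curve with
earliest-sample tie-breaking. Diagnostic acquisitions are cut to
[anchor − 60 s, anchor + 420 s] (an 8-minute window); therapeutic infusions
to [anchor − 120 s, anchor + 600 s]. Slow gravity infusions produce no bolus
peak, so a session may carry an `injection_start` time that overrides the
maximum as the anchor; the therapy simulator presets use this.

**Selective smoothing.** A Gaussian filter (default σ = 5 s, reflect-boundary
convolution, kernel truncated at 4σ) is applied only from 60 s after the
anchor onward, so the peak value is never smoothed. The σ default is a
deliberate choice: it suppresses the 1 Hz counting noise (white-noise variance
is reduced by ≈ 1/(2σ√π) ≈ 0.056) while leaving the ~minute-scale
plateau-approach dynamics intact. The splice at anchor + 60 s is a hard cut
with no cross-fade; the filter itself sees the whole windowed series, so
there is no boundary artefact at the splice. Values below the splice are
returned bit-identical.

**Plateau detection.** The plateau starts at the earliest sample, at or after
the anchor, from which every successive 1 s difference stays within
15 µSv/h (in absolute value — a plateau approached from below qualifies) for
60 consecutive seconds. Curves that never satisfy the rule are flagged
unstable and all plateau-based metrics are withheld rather than guessed. The
implementation is a cumulative-sum scan; the test suite proves it equal to an
exhaustive brute-force scan on 1,000 randomized curves.

**Metrics.** With the plateau means `DR_in_mean` and `DR_con_mean` (each arm
searched from the shared anchor, averaged from its plateau start to the
window end):

* `delta_p = DR_in_max − DR_in_mean`, the peak-to-plateau drop;
* `delta_p_nor = delta_p / (DR_in_max · A_inj / A_ref)`, its normalisation by
  peak height and injected activity, with **A_ref = 100 MBq**. The reference
  activity makes the metric dimensionally tidy and puts typical normal
  diagnostic administrations (peak ~20× plateau, ~187 MBq injected) near 0.5.
  It is exposed as `activity_ref` and recorded in report provenance;
* `delta_R_t = DR_in_mean − DR_con_mean`, the inter-arm plateau offset, and
  `delta_R_t_nor = delta_R_t / (A_inj / A_ref)` by symmetry;
* `t_star`, the time from the anchor to the injection-arm plateau start.

Therapy mode differs: an infusion curve has no representative peak, so
`DR_in_max`, `delta_p` and `delta_p_nor` are reported `NA`, and `delta_R_t`
is instead the mean *pointwise* smoothed inter-arm difference over the 10
minutes after the anchor (with a 5-minute variant and instantaneous
checkpoint values at 60–600 s). On constant-offset curves the 10-minute and
5-minute means agree exactly, which is why a 5-minute watch is already
decision-grade for stopping an infusion. The checkpoint values are defined as
instantaneous post-smoothing differences (not running means); both readings
are defensible, and the instantaneous one keeps the checkpoints independent
of window content.

**Classification.** Extravasation is flagged when `delta_p_nor ≤ 0.30` or
`delta_R_t ≥ 388 µSv/h`. The inequality directions follow from the class
statistics (extravasations have *smaller* normalised drops and *larger*
inter-arm offsets); values exactly at a threshold classify as extravasation
because a missed event costs a repeated examination while a false alarm costs
an image review. The two-detector default combines the metrics with OR;
single-detector sessions use `delta_p_nor` alone (with a warning when the
fall-back happens implicitly), therapy sessions `delta_R_t` alone. Thresholds
can be refit on any labelled cohort with `fit_threshold()`, a univariate
maximum-likelihood logistic fit whose operating point is the P = 0.5 crossing
−a/b; perfectly separated classes return the gap midpoint with a flag instead
of a diverging slope.

**Quantification.** Residual activity at the injection site comes either from
PET VOI statistics (`volume × mean concentration`, with the VOI segmented
upstream at 10% of the maximum-intensity voxel) or from SPECT counts through
a scanner calibration factor in cps/MBq; both are decay-corrected back to
injection time with the physical half-life only (no biological clearance — a
cautious choice without patient-specific kinetics). The diagnostic uptake
interval defaults to 60 min, the routine FDG protocol value, and is
configurable per session. Self-dose is the exact product of residual activity
and a sphere-model dose factor; dose factors are *inputs* (two-column table),
interpolated log-log in mass because they are close to a power law, and
clamped with a flag outside the table. The SUV correction is the
multiplicative identity `SUV_corr_coeff = A_inj / (A_inj − A_rs)` — the
unique form equivalent to subtracting the residual activity from the SUV
denominator — set to exactly 1 for normal administrations. Across a cohort
the coefficient is linear in `delta_R_t_nor` and in `1/delta_p_nor`;
`fit_suv_calibration()` fits that line by OLS and reports R² and RMSE
(√(SSE/(n−2))), with normal sessions entering as points at coefficient 1.

## What the simulator emulates — and what it does not

`simulate_session()` generates both arms on a shared generative model:

* a **systemic component** `S(t) = P·(1 − exp(−(t − t₀)/τ))` rising in *both*
  arms after the injection (default plateau P = 60 µSv/h diagnostic /
  150 therapy, τ = 30 s). Sharing the term between arms is the physically
  faithful choice — circulating activity perfuses both arms identically — and
  it pins the ground truth: the noise-free pointwise inter-arm difference
  equals the extravasation offset exactly once the bolus has washed out;
* a **bolus** `h·exp(−(t − t₀)/w)` on the injection arm only (default
  h = 1200 µSv/h, w = 10 s; h = 0 for therapy infusions);
* an **extravasation offset** added to the injection arm from the injection
  onward (0 for normal scenarios);
* multiplicative **lognormal noise** with mean 1 and CV 0.10 on every sample,
  matching the detectors' ~10% relative uncertainty, multiplicative so that
  low-rate contralateral samples stay non-negative.

Preset scenarios anchor the observed conditions: normal diagnostic
(Δpⁿᵒʳ ≈ 0.5), diagnostic extravasation (damped peak 600 plus offset
900 µSv/h), normal therapy (persistent 108 µSv/h offset, the observed normal
median) and therapy extravasation (828 µSv/h). Cohort sampling draws offsets
from lognormals anchored to the observed class medians and ranges
(median 46, sdlog 0.53 for normal; median 279, sdlog 1.62 for extravasation),
injected activities around 187 MBq, and clinical covariates independent of
everything else.

Two numerical consequences are worth knowing. First, exponential transients
never vanish exactly: the bolus tail and the equilibration deficit leak a few
µSv/h into the plateau means, so noise-free *generating-parameter* recovery
is accurate to ~1–2% (bounded by `P·τ/T_post`), while recovery of the
recorded noise-free *metric* vector is exact to machine precision (and is
independently confirmed in the tests by a loop-based oracle). Second, with
the heavy observed extravasation tail, offsets above roughly 4,500 µSv/h
produce smoothed successive differences larger than 15 µSv/h at 10% noise —
the stability rule then (correctly) never fires and those sessions are
flagged unstable instead of measured.

The simulator does **not** model detector physics (energy response, dead
time, scatter, geometry), motion artefacts, biological clearance, or infusion
speed variability. Passing tests on simulated cohorts therefore demonstrate
the correctness and stability of the *algorithmic chain*, not clinical
performance on real curves.

## Numerical choices and degenerate inputs

* Curves are validated (strictly increasing time, non-negative rates) and
  resampled onto integer seconds by linear interpolation when not natively
  1 Hz; curves shorter than the analysis window are rejected, not padded.
* CSV dialect detection: comma or semicolon delimiters, decimal commas in
  semicolon exports, float-second or ISO-8601 time columns.
* Peak ties break to the earliest sample; the peak is read from the raw
  (never the smoothed) curve.
* Logistic fits are IRLS via `stats::glm`, deterministic given data; the
  goodness statistic is McFadden's pseudo-R².
* `NA` propagates, never silently imputes: unstable curves, missing
  contralateral arms and out-of-data checkpoints all yield explicit `NA`
  (or errors naming the missing ingredient).

## Worked example

```{r example, eval = FALSE}
sim <- simulate_session(scenario_preset("extrav_diag", seed = 42))
report <- analyze_session(
  sim$session,
  quantification = list(source = "pet_voi", voi_volume = 14.9,
                        mean_concentration = 856960, elapsed = 60),
  dose_factor_table = tibble::tibble(
    mass_g = c(1, 5, 20, 50, 200),
    dose_factor_mGy_MBq = c(310, 95, 30, 14, 4.6)))
report
autoplot(sim$session, cfg = preprocess_config("diagnostic"))
```

Problem sizes used throughout the validation suite: 1,000 random curves for
the plateau-rule equivalence, 100 seeds per classification-rate check,
cohorts of 150–200 simulated sessions for the class statistics, 20 replicate
calibration fits of ~40 points. These sizes give stable estimates (binomial
and median standard errors of a few percent) at interactive runtimes.

## Known limitations

* The normalisation reference `A_ref = 100 MBq` is a convention; cohorts
  analysed with a different reference produce proportionally scaled
  `delta_p_nor` values and need matching thresholds.
* Dose factors are external inputs; the sphere model itself (and any
  voxel-level dosimetry) is out of scope.
* The SPECT path takes a count *rate* plus calibration factor; raw
  scanner-specific count exports must be converted upstream.
* The fixed 15 µSv/h stability threshold is absolute, so very high plateau
  levels (several mSv/h) at ~10% noise cannot satisfy it; such sessions are
  reported unstable by design.
* Single-detector mode cannot compute the inter-arm metrics; classification
  then rests on `delta_p_nor` alone.
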