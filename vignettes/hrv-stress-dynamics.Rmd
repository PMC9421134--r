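---
title: "Quantifying stress reactivity and recovery from ambulatory heart rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stress reactivity and recovery from ambulatory heart rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvstress)
```

## The problem

Vagally-mediated heart rate variability (vmHRV) indexes parasympathetic
influence on the heart and drops when people experience stress. Around a
naturalistic stressful event three phases can be distinguished: *resting*
(just before the event), *reactivity* (during it), and *recovery* (the time
until vmHRV returns to the pre-event level). Vagal tank theory predicts
which patterns are adaptive, and crucially predicts interactions: the
adaptive reactivity response depends on the metabolic demand of the event,
and the adaptive recovery course depends on whether vmHRV rose or fell
during the event. Testing these predictions outside the laboratory requires
a measurement pipeline that turns multi-day wearable ECG + accelerometer +
diary data into event-level outcomes, plus multilevel models that respect
the nesting of events within persons.

`hrvstress` implements that pipeline end to end, together with a
synthetic-cohort generator with known ground truth so every stage can be
validated without access to raw participant data.

## Measurement model

vmHRV is quantified by RMSSD, the root mean square of successive differences
of RR (inter-beat) intervals, in milliseconds. The pipeline works on
already-detected RR intervals:

1. **Artifact screening** (`screen_rr`). A beat is invalid when its RR falls
   outside an absolute range (default 300–2000 ms) or differs from the
   previous *valid* beat by more than `max_rel_change` (default 0.25).
   These defaults follow common ambulatory practice for
   successive-difference artifact rules; both are configurable because
   vendor implementations differ and rarely publish their constants.
2. **60-second aggregation** (`aggregate_minutes`). Each minute accumulates
   the count of valid beats and the sum of squared successive differences
   over *adjacent* valid beats within that minute. Pairs straddling a minute
   boundary are dropped, and a removed artifact breaks the pair on both
   sides, so screening can never manufacture large differences. Whether
   commercial aggregation pools differences across minute boundaries is
   undocumented; the within-minute convention is used consistently here and
   verified against a beat-level brute-force oracle.
3. **5-minute segments** (`segment_rmssd`). RMSSD over a segment pools the
   five minutes' sums: `sqrt(sum(ssd) / sum(pairs))`. A segment is missing
   when any minute is unworn, no pairs exist, or the valid-beat count falls
   below `min_coverage` (default 0.8) of the expected count (300 s divided
   by the mean valid RR). The coverage default is a deliberate choice: the
   source methodology deletes unusable segments without stating a
   threshold, and 80% is a common completeness requirement for short-term
   HRV.
4. **Log transform.** RMSSD is right-skewed; analyses use `ln(RMSSD)`. A
   zero RMSSD (constant RR, impossible in real recordings but easy to
   construct in toy data) maps to missing rather than `-Inf`.

## Events, reactivity and recovery

**Self-marked events.** Participants tap the sensor when they start feeling
stressed. Four validity rules exclude markers set (a) while the sensor was
not worn, (b) inside the 5-min reactivity segment of the previous kept
marker, (c) flagged in a diary as accidental, or (d) tied to an event
reported as lasting under 5 minutes. Rules (a), (c), (d) are evaluated
first and rule (b) sweeps chronologically over the survivors — this order
is deterministic and keeps the maximum number of markers; each exclusion
carries exactly one reason for transparent attrition accounting. Rule (b)
is read as "within the previous kept marker's reactivity segment"; the
alternative reading (any fixed 5-min bin) would make exclusions depend on
an arbitrary grid origin.

**Device-detected events.** To widen the range of metabolic demand, maximal
runs of minutes at or above 3 MET lasting at least 5 minutes (the standard
moderate-activity definition) are added as physically stressful events,
marked at the run's first minute. Runs overlapping a kept self-marker's
reactivity window are not double-counted.

**Reactivity.** Resting is the 5-min segment ending the minute before the
marker; reactivity is the 5-min segment starting the minute after it. The
marker minute itself is transitional and belongs to neither window. The
outcome is the raw difference `delta = reactivity − resting` (ms); the
direction dummy is 1 for an increase and 0 for a decrease. An exact tie is
coded 0 with a warning — ties cannot occur in real data and need a
deterministic rule only for synthetic input.

**Recovery.** The event end is the diary-reported duration (rounded up to
the 60-s grid) added to the marker minute. Diary reports are matched to
kept markers one-to-one in chronological order, to the closest marker
within ±120 min (inclusive); equidistant candidates resolve to the earlier
marker as the conservative causal candidate. From the event end, 5-min
windows shifted by 1 min are scanned: recovery is reached at the first
offset *k* whose RMSSD crosses the resting level in the restorative
direction — at/above resting after a decrease, at/below after an increase
(equality counts as recovered, since "returned to resting level" is
naturally inclusive). Censoring: *pile-up* when the next marker arrives
before the current window completes, *timeout* when `k` would exceed
120 min (`k = 120` is still allowed, consistent with observed recoveries up
to ~111 min), *missing* when the event end lies beyond the recording.
Undefined windows are skipped while `k` advances, and counted.

## Covariates and table assembly

Bihourly diaries (8 per day, first at 08:00) report on the preceding 2 h.
Substance (caffeine, alcohol, nicotine) and anticipated-stress flags are
set when any positive diary window overlaps the event's ±2 h window;
ambient noise uses only the preceding 2 h. All windows are closed
intervals. MET values above 79.8 (three times mean functional capacity in
exercise testing) are device artifacts and are set missing; the threshold
is exclusive. Chronic stress is the PSS-10 total (items 0–4, the four
positive items reverse-scored, summed to 0–40) standardized across the
sample. Event-level continuous measures are winsorized once at ±3 SD of
their pre-replacement moments; the log-transform precedes winsorization
(so outlier handling acts on the modeling scale). Resting lnRMSSD is
group-mean centered within person — coefficients then reflect
within-person deviations from one's typical resting level — and the other
continuous covariates are grand-mean centered. Rows with any missing model
variable are deleted listwise, matching the analysis convention for
ambulatory data whose missingness is too high for imputation.

## The two models

Reactivity (linear mixed model, REML, person random intercept):

    delta_rmssd ~ rest_c * react_met_c + rest_met_c + rest_supine_c +
      react_supine_c + time_in_study_c + caffeine + alcohol +
      anticipated_stress + ambient_noise + mvpa_hours_c + bmi_c +
      chronic_stress_z + (1 | person_id)

Recovery (Poisson GLMM, log link, Laplace approximation, uncensored
recoveries only):

    recovery_minutes ~ rest_c * direction + rest_met_c + recovery_met_c +
      time_in_study_c + (1 | person_id)

Recovery estimates are reported as incidence rate ratios (exponentiated
coefficients): an IRR above 1 is the multiplicative increase in expected
recovery minutes per unit predictor. The recovery formula is deliberately
lean — at ambulatory sample sizes, richer covariate sets routinely break
convergence of the Poisson model — and nicotine is coded but excluded from
both defaults for the same reason. Fixed-effect p-values use Satterthwaite
degrees of freedom for the linear model and Wald z for the Poisson model;
95% intervals are Wald (`estimate ± 1.96 SE`) in both. These are
documented choices, not claims about what any particular historical
analysis used; profile intervals would be more accurate in small samples
but are an order of magnitude slower in replicate studies. Random slopes
are omitted: daily-life event counts per person (~8 over four days) cannot
support them.

## The synthetic cohort

`simulate_cohort()` emulates a 4-day waking-hours (08:00–22:00) recording
per person:

* **Event schedule.** Self-marked events arrive as a Poisson process
  (default 2/day, i.e. ~8 markers over 4 days, matching daily-life marker
  frequency in student cohorts), never within 10 min of the waking-window
  edges and at least 15 min apart so algorithm tests are insulated from
  boundary effects (boundary behavior is tested separately with crafted
  fixtures). Durations are log-normal (meanlog 2.49, sdlog 1.05 → mean
  ≈ 21, SD ≈ 30 min), clipped to 1–240 min.
* **RMSSD trajectory.** Person-level resting RMSSD is log-normal around
  40 ms; each event carries a per-event resting deviation (SD 0.3 ln-ms).
  The event response follows the reactivity model itself:
  `delta = b0 + b_rest·rest_c + b_met·met_c + b_int·rest_c·met_c + e`
  with the defaults set to the reported effect magnitudes (−14.06,
  −3.55, −3.85 ms; residual SD 12.16; person intercept SD 6.07). MET is
  centered at 2.5 in these injections — the approximate grand mean over a
  mixed self-marked + device-detected event population — so pooled fits on
  simulated cohorts see one generating process across event types.
  Physical-activity bouts (uniform 3–7 MET, 5–30 min, ~2/day, independent
  of psychological events) depress the trajectory through the same
  response model. After an event the trajectory returns to baseline
  exponentially, with the half-life paced so the realized crossing time
  tracks a Poisson-drawn recovery duration whose log-mean is linear in
  centered resting lnRMSSD and the direction dummy (defaults log(8.72),
  log(4.30), log(0.88), log(0.24)). Draws above 120 min are flagged
  truncated, never resampled — censoring is an analysis-side concept.
* **RR synthesis.** Beats are `RR = mean_rr + e` with independent Gaussian
  perturbations of per-beat SD `target/√2`; successive differences of
  independent perturbations have variance `2σ²`, so expected RMSSD equals
  the target exactly. This deliberately ignores spectral HRV structure
  (LF/HF bands, respiratory sinus arrhythmia) — any generator with
  controllable RMSSD suffices to validate an RMSSD pipeline.
* **Observation noise.** Diary-reported start times and durations get
  Gaussian noise (SD 5 min each); a small fraction of markers is flagged
  accidental; block-wise non-wear removes ~5% of minutes; ~2% of beats are
  corrupted into artifacts the screening rules must catch.
* **Person table.** PSS-10 items, BMI (≈ N(23.3, 2.6)), weekly MVPA hours
  and demographics with student-cohort distributions.

The recovery-model simulator (`simulate_recovery_table`) defaults to a
person random-intercept SD of 0.5 rather than larger published estimates:
with the strong resting-lnRMSSD rate ratio, a larger person SD pushes many
simulated recoveries over the 120-min limit and the resulting selective
censoring would contaminate parameter-recovery checks; 0.5 keeps the
timeout fraction near the ~7% seen in ambulatory cohorts.

### What the generator does and does not establish

Passing tests on simulated cohorts show that the pipeline measures what it
defines and that the models recover known effects under the assumed
generating process. They do not show that real ECG artifacts resemble the
simulated ones, that real vmHRV dynamics are exponential returns around
step responses, or that diary errors are Gaussian. Two layers are therefore
validated differently: algorithmic stages (screening, RMSSD, event rules,
recovery scan) against exact brute-force oracles, and statistical stages
(the two mixed models) by parameter recovery on event-level tables drawn
directly from the model equations — the signal-level cohort exercises the
full chain end to end but its realized recovery times are driven by the
trajectory's return dynamics, so only the model-level route gives exact
ground truth for the Poisson coefficients.

## Numerical and degenerate-input choices

* Timestamps are floored to whole minutes on the 60-s grid; minute windows
  are 0-based and written `[start, start+4]` over minute indices.
* Reported durations are rounded up (`ceiling`) to whole minutes.
* `rmssd = 0` maps to missing lnRMSSD; all-constant winsorization input is
  returned unchanged; a constant chronic-stress sample standardizes to 0
  (the covariate then carries no information) rather than NaN.
* A rank-deficient model design errors naming the aliased columns; a
  near-zero random-intercept variance is reported as estimated, never
  hidden or "repaired".
* Tightening the artifact-screening threshold is *not* guaranteed to
  shrink the valid-beat set: the previous-valid reference chain can
  diverge between thresholds on pathological series. Monotonicity holds —
  and is tested — for series whose artifacts are isolated events between
  quiet stretches, which is the regime the rule is designed for.

## Problem sizes used in validation

Oracle equivalence runs on 200 random fixtures per algorithm. Parameter
recovery uses 60 persons × 10 events with 50–100 replicates (about 30,000
simulated events per check); null calibration uses 200 replicates at 40
persons × 8 events. The full-signal demonstration cohorts use 3–8 persons,
which keeps a complete simulate-screen-segment-model cycle within seconds
per person while still producing several hundred analyzable events.

## Known limitations

* The pipeline starts at RR intervals: R-peak detection and
  amplitude-based artifact rules are out of scope, and the screening rule
  is an RR-only adaptation of consecutive-change algorithms.
* Breathing pace, a known vmHRV covariate, is not modeled (ambulatory
  estimates of it are typically too incomplete to use).
* Recovery is modeled as a Poisson count with censored rows excluded, not
  with a survival model; pile-up beyond the censor flag is not attributed.
* The generator's circadian structure is minimal (day-level resting
  drift only), and its covariate flags are independent of events, so
  covariate-confounding scenarios must be constructed explicitly.
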