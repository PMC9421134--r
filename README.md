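# hrvstress

Stress reactivity and recovery dynamics from ambulatory heart rate
variability.

`hrvstress` is for researchers who study the physiological stress response
in daily life with wearable ECG + accelerometer devices and brief diaries.
It turns multi-day RR-interval recordings, minute-level activity (MET)
data, self-set stress markers and bihourly diary reports into event-level
outcomes — resting, reactivity, and recovery vagally-mediated HRV (vmHRV)
around each stressful event — and fits the corresponding multilevel
models. A synthetic-cohort generator with known ground truth makes every
stage testable without any participant data.

## What it computes

vmHRV is measured by RMSSD,

    RMSSD = sqrt( mean( (RR[i+1] - RR[i])^2 ) )    [ms]

computed on 5-minute segments after artifact screening and 60-second
aggregation. Around each stressful event (self-marked by a tap on the
sensor, or device-detected as a run of >= 3 MET lasting >= 5 min):

* **Resting** = RMSSD of the 5 min before the marker minute;
  **reactivity** = RMSSD of the 5 min after it. The outcome is
  `delta = reactivity - resting` (ms), with a 0/1 direction dummy.
* **Recovery time** = minutes after the diary-located event end until a
  1-min-shifted 5-min window crosses the resting level in the restorative
  direction, censored by pile-up (a new event arrives first) or timeout
  (120 min).
* **Models.** A linear mixed model predicts `delta` from group-mean
  centered resting lnRMSSD, reactivity MET, their interaction and
  covariates, with a person random intercept. A Poisson GLMM predicts
  recovery minutes from centered resting lnRMSSD, the direction dummy and
  their interaction; estimates are reported as incidence rate ratios
  (IRRs).

See `vignettes/hrv-stress-dynamics.Rmd` for the full measurement model,
parameter defaults, and design rationale.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort (8 persons, 4 days): `01_simulate.R` writes the cohort,
`02_screen_segment.R` screens and aggregates, `03_events_recovery.R`
builds events and recovery times, `04_models.R` fits both models, and
`05_parameter_recovery.R` checks the fits against ground truth. In R, the
same chain is three calls:

```r
library(hrvstress)
sim <- simulate_cohort(sim_config(n_persons = 8, seed = 20260926))
out <- run_pipeline(sim$dataset, study_config())
writeLines(out$manifest)
#> persons: 8
#> markers_set: 64
#> markers_excluded_not_worn: 1
#> markers_excluded_same_segment: 0
#> markers_excluded_accidental: 0
#> markers_excluded_too_short: 10
#> markers_kept: 53
#> device_events: 58
#> events_complete: 108
#> recoveries_computed: 53
#> recoveries_reached: 41
#> recoveries_pileup: 8
#> recoveries_timeout: 4
#> reactivity_rows: 108
#> recovery_rows_reached: 41
```

The manifest mirrors the attrition accounting an ambulatory study reports:
of 64 set markers, 11 are excluded (one not worn, ten tied to events
shorter than 5 min), 58 physically stressful events are added from MET
runs, and 41 of 53 recovery attempts reach the resting level (8 censored
by pile-up, 4 by the 120-min timeout).

```r
print(out$fits$reactivity)
#> <hrv_fit: gaussian mixed model, 108 obs / 8 persons>
#>                  term estimate    se    df        p   lower upper
#> 2              rest_c  -17.552 4.448 89.72 1.58e-04 -26.270 -8.83
#> 3         react_met_c   -4.042 0.613 90.49 2.78e-09  -5.243 -2.84
#> 15 rest_c:react_met_c   -6.024 2.176 90.85 6.83e-03 -10.290 -1.76
#> ...
```

Higher-than-usual resting vmHRV predicts a larger RMSSD drop during the
event (here −17.6 ms per ln-unit; the generator's true value is −14.06),
each MET of activity deepens the drop by ~4 ms (true −3.55), and the
negative interaction (true −3.85) says the resting-level effect steepens
with metabolic demand. At 8 persons the estimates are noisy; the
parameter-recovery script averages 30 replicates at 60 persons and
recovers −13.91, −4.04, and a recovery IRR of 4.35 (true 4.30).

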