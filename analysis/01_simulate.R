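#!/usr/bin/env Rscript
# Generate the synthetic ambulatory cohort used throughout the analysis:
# 8 persons, 4 days of waking-hours RR + accelerometer recording, tap
# markers, bihourly diaries, and the ground-truth event table.
library(hrvstress)

cfg <- sim_config(n_persons = 8, seed = 20260926 %% 2^31)
sim <- simulate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
write_cohort(sim$dataset, "results/cohort")
readr::write_csv(sim$truth$events, "results/cohort/truth_events.csv")

per_person <- table(factor(sim$dataset$markers$person_id,
                           levels = sim$dataset$persons$person_id))
cat(sprintf("persons: %d, days: %d\n", cfg$n_persons, cfg$n_days))
cat(sprintf("markers per person: mean %.1f, sd %.1f, range %d-%d\n",
            mean(per_person), sd(per_person), min(per_person),
            max(per_person)))
cat(sprintf("event durations (min): mean %.1f, sd %.1f, range %.0f-%.0f\n",
            mean(sim$truth$events$duration), sd(sim$truth$events$duration),
            min(sim$truth$events$duration), max(sim$truth$events$duration)))
cat(sprintf("beats simulated: %d\n", nrow(sim$dataset$rr)))
cat("cohort written to results/cohort/\n")
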