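#!/usr/bin/env Rscript
# Identify analyzable stressful events (self-marked and device-detected),
# build resting/reactivity records, and compute sliding-window recovery
# times with pile-up and timeout censoring. Reports the attrition at each
# stage the way an ambulatory-study flowchart would.
library(hrvstress)
library(dplyr)

ds <- read_cohort("results/cohort")
cfg <- study_config(fit_models = FALSE)
out <- run_pipeline(ds, cfg, out_dir = "results/pipeline")

cat("stage counts:\n")
writeLines(paste(" ", out$manifest))

kept <- out$markers[out$markers$kept, ]
cat(sprintf("\nexclusions: %d/%d markers (%.0f%%)\n",
            sum(!out$markers$kept), nrow(out$markers),
            100 * mean(!out$markers$kept)))
reached <- out$recoveries[out$recoveries$status == "reached", ]
if (nrow(reached) > 0)
  cat(sprintf("recovery minutes (reached): median %.1f, range %.0f-%.0f\n",
              median(reached$recovery_minutes),
              min(reached$recovery_minutes), max(reached$recovery_minutes)))
cat(sprintf("censored: %d pile-up, %d timeout, %d missing HRV\n",
            sum(out$recoveries$status == "pileup"),
            sum(out$recoveries$status == "timeout"),
            sum(out$recoveries$status == "missing_hrv")))
cat("tables written to results/pipeline/\n")
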