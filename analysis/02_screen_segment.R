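#!/usr/bin/env Rscript
# Artifact-screen the RR series and aggregate to 60-second resolution;
# report how much data the screening rules remove.
library(hrvstress)
library(dplyr)

ds <- read_cohort("results/cohort")
cfg <- study_config()

minutes_all <- lapply(unique(ds$persons$person_id), function(pid) {
  rr <- screen_rr(ds$rr[ds$rr$person_id == pid, ],
                  cfg$max_rel_change, cfg$rr_range)
  m <- aggregate_minutes(rr, ds$activity[ds$activity$person_id == pid, ])
  m$person_id <- pid
  cat(sprintf("%s: %d beats, %.2f%% flagged invalid\n", pid, nrow(rr),
              100 * mean(!rr$valid)))
  m
})
minutes <- bind_rows(minutes_all)
readr::write_csv(minutes, "results/minutes.csv")
cat(sprintf("\n%d minute records written to results/minutes.csv\n",
            nrow(minutes)))
cat(sprintf("worn coverage: %.1f%% of waking minutes\n",
            100 * mean(minutes$worn)))
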