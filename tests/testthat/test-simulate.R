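test_that("configuration validation rejects degenerate settings", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_days = 0), "n_days")
  expect_error(sim_config(waking_window = c(9, 9)), "waking window")
  expect_error(sim_config(missing_fraction = 1.2), "missing_fraction")
  expect_error(sim_config(recovery_halflife = 0), "halflife")
  expect_error(sim_config(mean_rr = 300), "mean_rr")
})

test_that("RR synthesis hits the RMSSD target via the sigma*sqrt(2) identity", {
  # constant target 0 -> constant series, RMSSD exactly 0
  set.seed(1)
  rr <- synthesize_rr(rep(0, 6), 800)
  expect_true(all(rr$rr == 800))
  m <- aggregate_minutes(dplyr::mutate(rr, valid = TRUE), flat_activity(0:5))
  expect_equal(segment_rmssd(m, 0)$rmssd, 0)

  # non-positive / invalid trajectories rejected
  expect_error(synthesize_rr(c(40, -1, 40)), "non-negative")
  expect_error(synthesize_rr(rep(40, 5), mean_rr = 200), "mean_rr")

  # Monte-Carlo check of the identity: mean realized RMSSD near 40
  set.seed(17)
  realized <- replicate(300, {
    rr <- synthesize_rr(rep(40, 5), 800)
    rr$valid <- TRUE
    segment_rmssd(aggregate_minutes(rr, flat_activity(0:4)), 0)$rmssd
  })
  expect_gt(mean(realized), 36)
  expect_lt(mean(realized), 44)
  # and tracks the target tightly on average (calibration property)
  expect_lt(abs(mean(realized) - 40) / 40, 0.15)
})

test_that("a step in the target trajectory shows up in realized RMSSD", {
  set.seed(23)
  drops <- replicate(60, {
    target <- c(rep(40, 10), rep(20, 10))
    rr <- synthesize_rr(target, 800)
    rr$valid <- TRUE
    m <- aggregate_minutes(rr, flat_activity(0:19))
    before <- segment_rmssd(m, 2)$rmssd
    after <- segment_rmssd(m, 12)$rmssd
    after < before
  })
  expect_gte(mean(drops), 0.95)
})

test_that("event response injection is the stated linear/Poisson model", {
  b0 <- c(intercept = 0, resting = 0, met = 0, interaction = 0)
  r0 <- c(intercept = 0, resting = 0, direction = 0, interaction = 0)
  set.seed(31)
  out <- inject_event_response(0.5, 2, b0, r0)
  expect_equal(out$delta_rmssd, 0)

  # linearity in MET: beta_met = -5, met 1 vs 3 -> deltas differ by -10
  bm <- c(intercept = 0, resting = 0, met = -5, interaction = 0)
  d1 <- inject_event_response(0, 1, bm, r0)$delta_rmssd
  d3 <- inject_event_response(0, 3, bm, r0)$delta_rmssd
  expect_equal(d3 - d1, -10)

  # interaction term multiplies centered rest by MET
  bi <- c(intercept = 1, resting = 2, met = 3, interaction = -4)
  d <- inject_event_response(0.5, 2, bi, r0)$delta_rmssd
  expect_equal(d, 1 + 2 * 0.5 + 3 * 2 + (-4) * 0.5 * 2)

  # Poisson recovery: log-mean 2 -> sample mean ~ e^2 within 3 SE
  set.seed(37)
  r2 <- c(intercept = 2, resting = 0, direction = 0, interaction = 0)
  draws <- replicate(10000, inject_event_response(0, 1, b0, r2)$recovery_minutes)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - exp(2)), 3 * se)

  # truncation is flagged, never resampled
  rbig <- c(intercept = log(200), resting = 0, direction = 0, interaction = 0)
  out <- inject_event_response(0, 1, b0, rbig)
  expect_true(out$truncated)
  expect_gt(out$recovery_minutes, 120)
})

test_that("cohort simulation is deterministic and honors the event rate", {
  cfg <- sim_config(n_persons = 2, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  # zero event rate -> no markers, empty truth
  sim0 <- simulate_cohort(sim_config(n_persons = 2, events_per_day_rate = 0,
                                     seed = 3))
  expect_equal(nrow(sim0$dataset$markers), 0)
  expect_equal(nrow(sim0$truth$events), 0)

  # configured rate 2/day over 4 days -> ~8 markers/person
  sim <- simulate_cohort(sim_config(n_persons = 50, n_days = 4,
                                    events_per_day_rate = 2,
                                    missing_fraction = 0,
                                    artifact_fraction = 0, seed = 11))
  per_person <- table(factor(sim$dataset$markers$person_id,
                             levels = sim$dataset$persons$person_id))
  m <- mean(per_person)
  se <- sd(per_person) / sqrt(length(per_person))
  expect_lt(abs(m - 8), 3 * se + 1e-9)
})

test_that("cohort structure is internally consistent", {
  sim <- simulate_cohort(sim_config(n_persons = 3, seed = 19))
  ds <- sim$dataset; tr <- sim$truth

  # every scheduled event has a marker at its start minute
  expect_equal(nrow(ds$markers), nrow(tr$events))
  expect_equal(sort(ds$markers$minute), sort(tr$events$start_minute))

  # every diary-reported event maps to exactly one true event
  reports <- ds$diaries[!is.na(ds$diaries$report_id), ]
  expect_true(all(reports$report_id %in% tr$events$event_id))
  expect_equal(length(unique(reports$report_id)), nrow(reports))
  # reported start deviates by the configured diary noise (bounded check)
  dev <- reports$reported_start -
    tr$events$start_minute[match(reports$report_id, tr$events$event_id)]
  expect_lt(max(abs(dev)), 6 * 5)

  # RR only inside each person's own worn waking minutes
  for (pid in unique(ds$persons$person_id)) {
    worn_min <- ds$activity$minute[ds$activity$worn &
                                   ds$activity$person_id == pid]
    rr_min <- floor(ds$rr$beat_time[ds$rr$person_id == pid] / 60)
    expect_true(all(rr_min %in% worn_min))
  }

  # fixed effects in truth equal the configuration
  cfg <- sim_config(n_persons = 3, seed = 19)
  expect_identical(tr$fixed_effects$reactivity, cfg$beta_reactivity)
  expect_identical(tr$fixed_effects$recovery, cfg$beta_recovery)
})

test_that("with no missingness or artifacts every event yields both segments", {
  sim <- simulate_cohort(sim_config(n_persons = 3, missing_fraction = 0,
                                    artifact_fraction = 0, seed = 29))
  for (pid in unique(sim$dataset$persons$person_id)) {
    rr <- screen_rr(sim$dataset$rr[sim$dataset$rr$person_id == pid, ])
    mins <- aggregate_minutes(rr,
      sim$dataset$activity[sim$dataset$activity$person_id == pid, ])
    evs <- sim$truth$events[sim$truth$events$person_id == pid, ]
    for (m in evs$start_minute) {
      rec <- build_event_record(m, mins)
      expect_true(rec$complete)
    }
  }
})
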