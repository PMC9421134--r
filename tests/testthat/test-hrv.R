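test_that("relative-change and absolute-range screening follow the rule", {
  s <- screen_rr(tibble::tibble(beat_time = 1:3, rr = c(800, 800, 800)))
  expect_true(all(s$valid))

  # middle beat jumps by 50% relative to previous valid beat
  s <- screen_rr(tibble::tibble(beat_time = 1:3, rr = c(800, 1200, 800)))
  expect_equal(s$valid, c(TRUE, FALSE, TRUE))

  # absolute range catches beats regardless of ratio
  s <- screen_rr(tibble::tibble(beat_time = 1:3, rr = c(800, 250, 800)))
  expect_equal(s$valid, c(TRUE, FALSE, TRUE))

  # comparison is against the previous VALID beat, not the previous beat
  s <- screen_rr(tibble::tibble(beat_time = 1:4, rr = c(800, 2500, 980, 800)))
  expect_equal(s$valid, c(TRUE, FALSE, TRUE, TRUE))

  # first beat valid iff in range
  s <- screen_rr(tibble::tibble(beat_time = 1:2, rr = c(250, 800)))
  expect_equal(s$valid, c(FALSE, TRUE))

  expect_error(screen_rr(tibble::tibble(beat_time = numeric(), rr = numeric())),
               "empty")
})

test_that("screening is monotone in the threshold for isolated artifacts", {
  # baseline jitter stays below the tighter threshold; artifacts are
  # isolated spikes (rejected by both) or single mid-size steps (rejected
  # only by the tighter rule), separated by quiet stretches so the
  # previous-valid reference re-synchronizes between thresholds
  set.seed(11)
  for (rep in 1:20) {
    base <- 800 + runif(90, -25, 25)
    art_pos <- seq(10, 80, by = 10)
    kind <- sample(c("spike", "step"), length(art_pos), replace = TRUE)
    rr_vals <- base
    rr_vals[art_pos[kind == "spike"]] <- base[art_pos[kind == "spike"]] * 2
    rr_vals[art_pos[kind == "step"]] <- base[art_pos[kind == "step"]] * 1.2
    rr <- tibble::tibble(beat_time = seq_along(rr_vals), rr = rr_vals)
    v_loose <- screen_rr(rr, max_rel_change = 0.25)$valid
    v_tight <- screen_rr(rr, max_rel_change = 0.10)$valid
    expect_true(all(v_loose[v_tight]))        # tight set is a subset
    expect_lte(sum(v_tight), sum(v_loose))
  }
})

test_that("minute aggregation counts beats and within-minute pairs", {
  # hand-computed: diffs 10, -20, 15 -> 100 + 400 + 225 = 725
  rr <- tibble::tibble(beat_time = c(10, 10.8, 11.6, 12.4),
                       rr = c(800, 810, 790, 805), valid = TRUE)
  m <- aggregate_minutes(rr, flat_activity(0:1))
  expect_equal(m$n_valid_beats[m$minute == 0], 4)
  expect_equal(m$sum_sq_succ_diff[m$minute == 0], 725)
  expect_equal(m$n_succ_pairs[m$minute == 0], 3)

  # constant RR -> zero dispersion
  rr <- tibble::tibble(beat_time = cumsum(rep(1, 60)), rr = 1000, valid = TRUE)
  m <- aggregate_minutes(rr, flat_activity(0:1))
  expect_equal(m$n_valid_beats[m$minute == 0], 59)  # beat at 60 s is minute 1
  expect_equal(m$sum_sq_succ_diff[m$minute == 0], 0)

  # a pair straddling the boundary contributes to neither minute
  rr <- tibble::tibble(beat_time = c(59.5, 60.5), rr = c(800, 900), valid = TRUE)
  m <- aggregate_minutes(rr, flat_activity(0:1))
  expect_equal(sum(m$n_succ_pairs), 0)

  # an invalid beat breaks the pairs on both sides
  rr <- tibble::tibble(beat_time = c(10, 10.8, 11.6), rr = c(800, 2500, 805),
                       valid = c(TRUE, FALSE, TRUE))
  m <- aggregate_minutes(rr, flat_activity(0:1))
  expect_equal(sum(m$n_succ_pairs), 0)

  expect_error(aggregate_minutes(
    tibble::tibble(beat_time = 5000, rr = 800, valid = TRUE),
    flat_activity(0:3)), "disjoint")
})

test_that("segment RMSSD pools the five minutes and applies coverage", {
  # constant RR -> rmssd exactly 0, ln undefined
  rr <- tibble::tibble(beat_time = cumsum(rep(0.8, 380)), rr = 800, valid = TRUE)
  m <- aggregate_minutes(rr, flat_activity(0:5))
  seg <- segment_rmssd(m, 0)
  expect_equal(seg$rmssd, 0)
  expect_true(is.na(seg$ln_rmssd))

  # hand example: one minute with ssd 725 over 3 pairs, rest constant;
  # with 236 zero-diff pairs elsewhere, rmssd = sqrt(725 / 239)
  m <- flat_activity(0:4)
  m$n_valid_beats <- c(4, rep(60, 4))
  m$sum_sq_succ_diff <- c(725, 0, 0, 0, 0)
  m$n_succ_pairs <- c(3, 59, 59, 59, 59)
  m$sum_rr_valid <- m$n_valid_beats * 800
  seg <- segment_rmssd(m, 0, min_coverage = 0.5)
  expect_equal(seg$rmssd, sqrt(725 / 239), tolerance = 1e-12)

  # any unworn minute -> undefined
  m$worn[3] <- FALSE
  expect_false(segment_rmssd(m, 0)$defined)

  # insufficient coverage -> undefined
  m2 <- flat_activity(0:4)
  m2$n_valid_beats <- rep(30, 5)   # ~375 expected at 800 ms
  m2$sum_sq_succ_diff <- rep(100, 5)
  m2$n_succ_pairs <- rep(29, 5)
  m2$sum_rr_valid <- m2$n_valid_beats * 800
  expect_false(segment_rmssd(m2, 0, min_coverage = 0.8)$defined)
  expect_true(segment_rmssd(m2, 0, min_coverage = 0.3)$defined)
})

test_that("segment RMSSD equals the brute-force beat-level oracle", {
  set.seed(21)
  for (rep in 1:50) {
    rr <- random_rr_fixture(n_min = 6)
    m <- aggregate_minutes(rr, flat_activity(0:5))
    seg <- segment_rmssd(m, 0, min_coverage = 0)
    oracle <- oracle_rmssd_from_beats(rr$beat_time, rr$rr, rr$valid, 0)
    if (is.na(oracle)) {
      expect_false(seg$defined)
    } else {
      expect_equal(seg$rmssd, oracle, tolerance = 1e-9)
    }
  }
})

test_that("RMSSD is scale-equivariant in the differences and shift-invariant", {
  set.seed(31)
  rr <- random_rr_fixture(n_min = 6, invalid_prob = 0)
  m1 <- aggregate_minutes(rr, flat_activity(0:5))
  base <- segment_rmssd(m1, 0, min_coverage = 0)$rmssd

  # adding a constant to all RR leaves differences unchanged
  rr_shift <- rr
  rr_shift$rr <- rr$rr + 100
  m2 <- aggregate_minutes(rr_shift, flat_activity(0:5))
  expect_equal(segment_rmssd(m2, 0, min_coverage = 0)$rmssd, base,
               tolerance = 1e-9)

  # scaling deviations around the mean by c scales rmssd by |c|
  mu <- mean(rr$rr)
  rr_scaled <- rr
  rr_scaled$rr <- mu + 3 * (rr$rr - mu)
  m3 <- aggregate_minutes(rr_scaled, flat_activity(0:5))
  expect_equal(segment_rmssd(m3, 0, min_coverage = 0)$rmssd, 3 * base,
               tolerance = 1e-9)
})

test_that("log transform handles the boundary cases", {
  expect_equal(ln_rmssd(1), 0)
  expect_equal(ln_rmssd(exp(1)), 1)
  expect_equal(ln_rmssd(40.74), log(40.74))
  expect_true(is.na(ln_rmssd(0)))
  expect_equal(ln_rmssd(c(1, 0, NA, exp(2))), c(0, NA, NA, 2))
})
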