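diary_fixture <- function(minutes, flag, value = 1) {
  flags <- c("caffeine", "alcohol", "nicotine", "anticipated_stress",
             "ambient_noise")
  d <- tibble::tibble(diary_minute = minutes)
  for (f in flags) d[[f]] <- 0
  d[[flag]][length(minutes)] <- value
  d
}

test_that("substance flags use +/- 2 h windows, noise the preceding 2 h only", {
  # caffeine reported in the diary covering 90 min before the event
  d <- diary_fixture(c(480, 600), "caffeine")  # positive diary at 600
  expect_equal(code_event_flags(690, d)$caffeine, 1L)

  # positive diary whose look-back window ends 60 min after the event:
  # overlaps the +/- 2 h window but NOT the preceding-only window
  d <- diary_fixture(c(480, 660), "ambient_noise")  # window [540, 660]
  expect_equal(code_event_flags(480, d)$ambient_noise, 0L)
  d2 <- diary_fixture(c(480, 660), "caffeine")
  expect_equal(code_event_flags(480, d2)$caffeine, 1L)

  # window boundaries are closed: diary look-back ending exactly 120 min
  # before the event still counts
  d <- diary_fixture(c(200), "alcohol")  # window [80, 200]
  expect_equal(code_event_flags(320, d)$alcohol, 1L)
  expect_equal(code_event_flags(321, d)$alcohol, 0L)

  # no positive reports -> all flags zero; recoding is idempotent
  d <- diary_fixture(c(480, 600), "caffeine", value = 0)
  f1 <- code_event_flags(500, d)
  expect_true(all(unlist(f1) == 0))
  expect_identical(code_event_flags(500, d), f1)
})

test_that("winsorization clips at 3 SD of the pre-replacement moments", {
  set.seed(1)
  x <- rnorm(50)                      # everything within 3 SD
  expect_equal(winsorize_3sd(x), x)
  # symmetric outliers clip to the symmetric bounds
  x <- c(rep(c(-1, 1), 10), 15, -15)
  m <- mean(x); s <- sd(x)
  expect_lt(3 * s, 15)
  w <- winsorize_3sd(x)
  expect_equal(w[21], m + 3 * s)
  expect_equal(w[22], m - 3 * s)
  expect_equal(w[1:20], x[1:20])
  # single pass: re-clipping on the ORIGINAL moments is a no-op
  expect_equal(pmin(pmax(w, m - 3 * s), m + 3 * s), w, tolerance = 1e-12)
  expect_true(all(w >= m - 3 * s & w <= m + 3 * s))
  # constant series unchanged
  expect_equal(winsorize_3sd(rep(2, 10)), rep(2, 10))
  # NAs pass through
  x <- c(NA, rnorm(20))
  expect_true(is.na(winsorize_3sd(x)[1]))
})

test_that("centering subtracts group or grand means exactly", {
  x <- c(3.0, 3.5, 4.0)
  out <- center_values(x, group = rep("a", 3))
  expect_equal(as.numeric(out), c(-0.5, 0, 0.5))

  expect_equal(as.numeric(center_values(rep(7, 5))), rep(0, 5))

  set.seed(2)
  g <- rep(letters[1:5], each = 8)
  x <- rnorm(40, as.integer(factor(g)))
  cx <- center_values(x, g)
  sums <- tapply(cx, g, sum)
  expect_true(all(abs(sums) < 1e-10))
})

test_that("MET screening removes only values above 79.8", {
  expect_equal(screen_met(c(6.5, 79.8, 80, 200, NA)),
               c(6.5, 79.8, NA, NA, NA))
  set.seed(3)
  x <- runif(100, 0, 79.8)
  expect_equal(screen_met(x), x)
})

test_that("PSS-10 scoring reverses the positive items and standardizes", {
  # all zeros after reversal: raw 0 on negative items, 4 on items 4,5,7,8
  items <- matrix(0, 1, 10)
  items[, c(4, 5, 7, 8)] <- 4
  expect_equal(score_pss10(items), 0)
  # maximum total
  items <- matrix(4, 1, 10)
  items[, c(4, 5, 7, 8)] <- 0
  expect_equal(score_pss10(items), 40)
  # missing item propagates
  items <- matrix(2, 2, 10)
  items[2, 3] <- NA
  expect_true(is.na(score_pss10(items)[2]))
  expect_error(score_pss10(matrix(5, 1, 10)), "0-4")

  set.seed(4)
  totals <- sample(7:39, 30, replace = TRUE)
  z <- standardize(totals)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("assembled tables apply listwise deletion and day conversion", {
  ev <- tibble::tibble(
    person_id = rep(c("P1", "P2"), each = 3),
    event_id = 1:6, source = "self",
    marker_minute = c(480, 1920, 3360, 480, 2880, 4320),
    rest_rmssd = 40, rest_ln_rmssd = log(c(35, 40, 45, 38, 42, 50)),
    rest_met = c(1.5, 1.4, 90, 1.2, 1.6, 1.3),   # one improbable MET
    rest_supine = 0, react_rmssd = 42,
    react_ln_rmssd = log(42), react_met = 1.7, react_supine = 0,
    delta_rmssd = c(2, -3, 5, 1, NA, 4),          # one missing outcome
    direction = c(1L, 0L, 1L, 1L, NA, 1L), complete = TRUE,
    caffeine = 0L, alcohol = 0L, nicotine = 0L, anticipated_stress = 0L,
    ambient_noise = 0L)
  persons <- tibble::tibble(person_id = c("P1", "P2"), bmi = c(22, 25),
                            mvpa_hours = c(4, 6), chronic_stress_z = c(-1, 1),
                            first_minute = c(480, 480))
  rec <- tibble::tibble(person_id = c("P1", "P1"), event_id = c(1, 2),
                        recovery_minutes = c(10, NA),
                        status = c("reached", "timeout"),
                        recovery_met = c(1.5, NA), recovery_supine = c(0, NA))
  out <- assemble_analysis_tables(ev, rec, persons)
  # events 3 (MET screened) and 5 (missing outcome) drop listwise
  expect_equal(sort(out$reactivity$event_id), c(1, 2, 4, 6))
  expect_equal(nrow(out$recovery), 2)
  expect_setequal(out$recovery$status, c("reached", "timeout"))

  expect_error(assemble_analysis_tables(ev[ev$complete == FALSE, ], rec[0, ],
                                        persons),
               "empty")
})

test_that("time in study converts minutes to days from the first minute", {
  ev <- tibble::tibble(
    person_id = "P1", event_id = 1:2, source = "self",
    marker_minute = c(480, 480 + 2880),
    rest_rmssd = 40, rest_ln_rmssd = log(c(35, 45)), rest_met = 1.5,
    rest_supine = 0, react_rmssd = 42, react_ln_rmssd = log(42),
    react_met = 1.7, react_supine = 0, delta_rmssd = c(2, -1),
    direction = c(1L, 0L), complete = TRUE)
  persons <- tibble::tibble(person_id = "P1", bmi = 22, mvpa_hours = 4,
                            chronic_stress_z = 0, first_minute = 480)
  out <- assemble_analysis_tables(ev, tibble::tibble(), persons)
  # centered: raw values 0 and 2 days -> centered -1 and +1
  expect_equal(sort(out$reactivity$time_in_study_c), c(-1, 1))
  # with no rows lost, group-centered resting lnRMSSD sums to zero in person
  expect_equal(sum(out$reactivity$rest_c), 0, tolerance = 1e-12)
})
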