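#' Configuration for the synthetic ambulatory cohort
#'
#' Bundles and validates every tunable of the generator. Defaults emulate a
#' 4-day waking-hours wearable study of students: roughly 8 self-marked
#' stressful events per person over the 4 days (Poisson rate 2/day),
#' log-normal event durations with mean about 21 and SD about 30 minutes,
#' between-person resting RMSSD log-normal around 40 ms, and reactivity /
#' recovery effect sizes of the magnitude reported for daily-life cohorts
#' (resting-lnRMSSD slope -14.06 ms, MET slope -3.55 ms, interaction
#' -3.85 ms; recovery log-rate intercept log(8.72), resting slope
#' log(4.30), direction log(0.88), interaction log(0.24)).
#'
#' @param n_persons Number of persons.
#' @param n_days Days of recording per person. Default 4.
#' @param waking_window Start/end clock hours of wear time. Default c(8, 22).
#' @param events_per_day_rate Poisson rate of self-marked events per day.
#' @param event_duration_lognormal `c(meanlog, sdlog)` of durations (min).
#' @param base_rmssd_lognormal `c(meanlog, sdlog)` of person resting RMSSD (ms).
#' @param within_person_rest_sd SD of per-event resting lnRMSSD deviations.
#' @param mean_rr Mean RR interval in ms. Default 800.
#' @param beta_reactivity Named vector `intercept`, `resting`, `met`,
#'   `interaction`: ms of delta-RMSSD per unit predictor.
#' @param reactivity_noise_sd Residual SD of delta-RMSSD (ms).
#' @param person_intercept_sd SD of the person-level reactivity intercept (ms).
#' @param beta_recovery Named vector `intercept`, `resting`, `direction`,
#'   `interaction` on the log-rate scale for recovery minutes.
#' @param recovery_person_sd SD of the person-level log-rate intercept.
#' @param recovery_halflife Half-life (min) of the post-event exponential
#'   return of the RMSSD trajectory.
#' @param recovery_timeout Censoring limit in minutes. Default 120.
#' @param diary_time_noise_sd SD (min) of diary-reported start times.
#' @param diary_duration_noise_sd SD (min) of diary-reported durations.
#' @param accident_prob Probability a marker is flagged accidental.
#' @param missing_fraction Fraction of waking minutes lost to non-wear.
#' @param artifact_fraction Fraction of beats corrupted into artifacts.
#' @param met_bouts_per_day Poisson rate of moderate-activity bouts per day.
#' @param met_center Grand-mean MET about which the reactivity betas are
#'   expressed (the fitted model centers MET); event responses are injected
#'   with `met - met_center`. Default 2.5, the approximate mean over a
#'   mixed self-marked plus device-detected event population.
#' @param covariate_prevalences Named 0-1 vector of per-diary flag
#'   probabilities (`caffeine`, `alcohol`, `nicotine`, `anticipated_stress`,
#'   `ambient_noise`).
#' @param seed Integer seed; identical configs give identical datasets.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_persons = 8,
                       n_days = 4,
                       waking_window = c(8, 22),
                       events_per_day_rate = 2,
                       event_duration_lognormal = c(2.49, 1.05),
                       base_rmssd_lognormal = c(log(40), 0.45),
                       within_person_rest_sd = 0.3,
                       mean_rr = 800,
                       beta_reactivity = c(intercept = -7.06, resting = -14.06,
                                           met = -3.55, interaction = -3.85),
                       reactivity_noise_sd = 12.16,
                       person_intercept_sd = 6.07,
                       beta_recovery = c(intercept = log(8.72),
                                         resting = log(4.30),
                                         direction = log(0.88),
                                         interaction = log(0.24)),
                       recovery_person_sd = 0.5,
                       recovery_halflife = 10,
                       recovery_timeout = 120,
                       diary_time_noise_sd = 5,
                       diary_duration_noise_sd = 5,
                       accident_prob = 0.03,
                       missing_fraction = 0.05,
                       artifact_fraction = 0.02,
                       met_bouts_per_day = 2,
                       met_center = 2.5,
                       covariate_prevalences = c(caffeine = 0.27,
                                                 alcohol = 0.04,
                                                 nicotine = 0.08,
                                                 anticipated_stress = 0.27,
                                                 ambient_noise = 0.08),
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_days < 1) stop("configuration error: n_days must be >= 1")
  if (length(cfg$waking_window) != 2 ||
      cfg$waking_window[2] <= cfg$waking_window[1])
    stop("configuration error: empty waking window")
  if (cfg$events_per_day_rate < 0) stop("configuration error: negative rate")
  for (f in c("missing_fraction", "artifact_fraction", "accident_prob"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: ", f, " outside [0, 1]")
  if (any(cfg$covariate_prevalences < 0 | cfg$covariate_prevalences > 1))
    stop("configuration error: covariate prevalence outside [0, 1]")
  if (cfg$recovery_halflife <= 0)
    stop("configuration error: recovery_halflife must be positive")
  if (cfg$mean_rr < 400 || cfg$mean_rr > 1500)
    stop("configuration error: mean_rr outside 400-1500 ms")
  structure(cfg, class = "sim_config")
}

#' Synthesize an RR-interval series with a target RMSSD trajectory
#'
#' Generates beats as `RR = mean_rr + e`, with independent Gaussian
#' perturbations whose per-beat SD in the minute t is
#' `target[t] / sqrt(2)`. Successive differences of independent
#' perturbations have variance `2 * sigma^2`, so the expected RMSSD in each
#' minute equals the target exactly; realized 5-min RMSSD lies within 15%
#' of the target in expectation. A constant target of 0 yields a constant
#' series with RMSSD exactly 0. Beat times are the cumulative sum of the
#' realized intervals.
#'
#' @param target_rmssd Per-minute target RMSSD trajectory (ms, >= 0).
#' @param mean_rr Mean RR in ms (400-1500).
#' @param offset_sec Added to all beat times (places the block on a study
#'   timeline). Default 0.
#' @return Tibble with `beat_time` (seconds) and `rr` (ms).
#' @export
synthesize_rr <- function(target_rmssd, mean_rr = 800, offset_sec = 0) {
  if (any(is.na(target_rmssd)) || any(target_rmssd < 0))
    stop("target trajectory must be non-negative")
  if (mean_rr < 400 || mean_rr > 1500) stop("mean_rr outside 400-1500 ms")
  total_sec <- length(target_rmssd) * 60
  n <- ceiling(total_sec * 1000 / mean_rr) + 2L
  nominal <- cumsum(rep(mean_rr / 1000, n))
  keep <- nominal <= total_sec
  nominal <- nominal[keep]
  n <- length(nominal)
  minute <- pmin(floor(nominal / 60) + 1L, length(target_rmssd))
  sigma <- target_rmssd[minute] / sqrt(2)
  rr <- mean_rr + stats::rnorm(n, 0, 1) * sigma
  rr <- pmax(rr, 250)  # guard against non-physiological negatives
  bt <- cumsum(rr) / 1000
  keep <- bt < total_sec  # realized drift must not spill past the block
  tibble::tibble(beat_time = offset_sec + bt[keep], rr = rr[keep])
}

#' Draw an event's reactivity and recovery response from the ground truth
#'
#' The reactivity outcome follows the linear model
#' `delta = b0 + b_rest * rest_c + b_met * met + b_int * rest_c * met + e`,
#' and recovery minutes are drawn from a Poisson whose log-mean is linear
#' in centered resting lnRMSSD, the direction dummy, and their interaction;
#' draws above the timeout are kept but flagged truncated (censoring
#' happens analysis-side, not by resampling).
#'
#' @param rest_c Centered resting lnRMSSD (ln-ms).
#' @param met_during Mean MET during the reactivity segment.
#' @param beta_reactivity,beta_recovery Named coefficient vectors as in
#'   [sim_config()].
#' @param noise_sd Residual SD of delta (ms); 0 gives the deterministic part.
#' @param person_effect Person-level reactivity intercept deviation (ms).
#' @param recovery_person_effect Person-level log-rate deviation.
#' @param timeout Truncation flag threshold in minutes. Default 120.
#' @return One-row tibble: `delta_rmssd`, `direction`, `recovery_minutes`,
#'   `truncated`.
#' @export
inject_event_response <- function(rest_c, met_during, beta_reactivity,
                                  beta_recovery, noise_sd = 0,
                                  person_effect = 0,
                                  recovery_person_effect = 0,
                                  timeout = 120) {
  stopifnot(all(is.finite(beta_reactivity)), all(is.finite(beta_recovery)))
  delta <- beta_reactivity[["intercept"]] + person_effect +
    beta_reactivity[["resting"]] * rest_c +
    beta_reactivity[["met"]] * met_during +
    beta_reactivity[["interaction"]] * rest_c * met_during +
    (if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0)
  direction <- as.integer(delta > 0)
  log_mu <- beta_recovery[["intercept"]] + recovery_person_effect +
    beta_recovery[["resting"]] * rest_c +
    beta_recovery[["direction"]] * direction +
    beta_recovery[["interaction"]] * rest_c * direction
  rec <- stats::rpois(1, exp(log_mu))
  tibble::tibble(delta_rmssd = delta, direction = direction,
                 recovery_minutes = rec, truncated = rec > timeout)
}

# schedule event start minutes for one day: inside the waking window with a
# 10-min margin from both edges, starts at least 15 min apart
schedule_day_events <- function(n, win_lo, win_hi) {
  if (n == 0) return(numeric())
  lo <- win_lo + 10
  hi <- win_hi - 10
  for (tries in 1:50) {
    starts <- sort(floor(stats::runif(n, lo, hi)))
    if (n == 1 || min(diff(starts)) >= 15) return(starts)
  }
  starts[c(TRUE, diff(starts) >= 15)]
}

#' Simulate a multi-person ambulatory cohort with known ground truth
#'
#' Builds, person by person, a 4-day (configurable) waking-hours recording:
#' a per-minute RMSSD target trajectory carrying each scheduled event's
#' reactivity step and an exponential post-event return, an RR-interval
#' series realizing that trajectory (with optional artifact beats), a
#' minute-level activity table (baseline ~1.3 MET with moderate bouts,
#' supine fractions, wear state with block-wise non-wear), a tap marker at
#' each event's start minute, bihourly diaries (8/day, first at 08:00)
#' reporting each event since the previous prompt with noisy start time and
#' duration plus substance/noise/anticipation flags, and a person-level
#' table (PSS-10 items, BMI, MVPA, sex, age). The returned ground truth
#' aligns index-for-index with the scheduled events.
#'
#' All study timestamps are minutes since day-0 midnight; RR beat times are
#' seconds on the same axis.
#'
#' @param config A [sim_config()] object.
#' @return List with `dataset` (tibbles `rr`, `activity`, `markers`,
#'   `diaries`, `persons`) and `truth` (list `events`, `persons`,
#'   `fixed_effects`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  win_lo_min <- config$waking_window[1] * 60
  win_hi_min <- config$waking_window[2] * 60
  day_minutes <- win_hi_min - win_lo_min

  rr_all <- list(); act_all <- list(); mark_all <- list(); diary_all <- list()
  pers_rows <- list(); truth_ev <- list(); truth_pers <- list()
  ev_counter <- 0L

  for (p in seq_len(config$n_persons)) {
    pid <- sprintf("P%03d", p)
    rest_ln_mean <- stats::rnorm(1, config$base_rmssd_lognormal[1],
                                 config$base_rmssd_lognormal[2])
    react_int <- stats::rnorm(1, 0, config$person_intercept_sd)
    rec_int <- stats::rnorm(1, 0, config$recovery_person_sd)

    # --- event schedule over all days ---
    ev <- list()
    for (d in seq_len(config$n_days)) {
      n_ev <- stats::rpois(1, config$events_per_day_rate)
      starts <- schedule_day_events(n_ev, (d - 1) * 1440 + win_lo_min,
                                    (d - 1) * 1440 + win_hi_min)
      for (s in starts) {
        dur <- stats::rlnorm(1, config$event_duration_lognormal[1],
                             config$event_duration_lognormal[2])
        dur <- min(max(dur, 1), 240)
        ev[[length(ev) + 1]] <- list(day = d, start = s,
                                     end = s + ceiling(dur), duration = dur)
      }
    }

    # --- activity: minute grid over waking windows ---
    act <- do.call(rbind, lapply(seq_len(config$n_days), function(d) {
      mins <- ((d - 1) * 1440 + win_lo_min):((d - 1) * 1440 + win_hi_min - 1)
      tibble::tibble(minute = mins, day = d)
    }))
    act$met <- pmax(1, 1.3 + stats::rnorm(nrow(act), 0, 0.12))
    bouts <- list()
    for (d in seq_len(config$n_days)) {
      n_bouts <- stats::rpois(1, config$met_bouts_per_day)
      for (b in seq_len(n_bouts)) {
        b_start <- floor(stats::runif(1, (d - 1) * 1440 + win_lo_min,
                                      (d - 1) * 1440 + win_hi_min - 30))
        b_len <- sample(5:30, 1)
        b_level <- stats::runif(1, 3, 7)
        sel <- act$minute >= b_start & act$minute < b_start + b_len
        act$met[sel] <- b_level + stats::rnorm(sum(sel), 0, 0.2)
        bouts[[length(bouts) + 1]] <- list(day = d, start = b_start,
                                           len = b_len, level = b_level)
      }
    }
    act$supine_fraction <- ifelse(stats::runif(nrow(act)) < 0.03,
                                  stats::runif(nrow(act)), 0)
    act$worn <- TRUE
    if (config$missing_fraction > 0) {
      n_missing <- round(config$missing_fraction * nrow(act))
      while (sum(!act$worn) < n_missing) {
        blk_start <- sample(nrow(act), 1)
        blk_len <- 1 + stats::rgeom(1, 1 / 10)
        act$worn[blk_start:min(nrow(act), blk_start + blk_len - 1)] <- FALSE
      }
    }

    # --- per-minute RMSSD target trajectory (built on the waking grid) ---
    rest_ln_slow <- stats::rnorm(config$n_days, 0, config$within_person_rest_sd / 2)
    traj_ln <- rest_ln_mean + rest_ln_slow[act$day]
    target <- exp(traj_ln)
    ev_truth_p <- list()
    for (e in ev) {
      idx_ev <- which(act$minute >= e$start & act$minute <= e$end)
      rest_dev <- stats::rnorm(1, 0, config$within_person_rest_sd)
      rest_c_true <- rest_dev  # deviation from person mean, by construction
      target[act$minute >= e$start - 10 & act$minute < e$start] <-
        exp(rest_ln_mean + rest_dev)
      met_during <- mean(act$met[act$minute >= e$start + 1 &
                                 act$minute <= e$start + 5])
      resp <- inject_event_response(rest_c_true,
                                    met_during - config$met_center,
                                    config$beta_reactivity,
                                    config$beta_recovery,
                                    noise_sd = config$reactivity_noise_sd,
                                    person_effect = react_int,
                                    recovery_person_effect = rec_int,
                                    timeout = config$recovery_timeout)
      base_ev <- exp(rest_ln_mean + rest_dev)
      target[idx_ev] <- pmax(base_ev + resp$delta_rmssd, 3)
      # post-event exponential return paced so the realized crossing time
      # tracks the drawn recovery minutes (crossing occurs after roughly
      # 2-3 half-lives once the response falls under measurement noise)
      halflife <- max(config$recovery_halflife / 5,
                      min(resp$recovery_minutes, config$recovery_timeout) / 2.5)
      idx_post <- which(act$minute > e$end & act$minute <= e$end + 180 &
                        act$day == e$day)
      if (length(idx_post) > 0) {
        tpost <- act$minute[idx_post] - e$end
        target[idx_post] <- pmax(
          base_ev + resp$delta_rmssd * 2^(-tpost / halflife), 3)
      }
      ev_counter <- ev_counter + 1L
      ev_truth_p[[length(ev_truth_p) + 1]] <- tibble::tibble(
        person_id = pid, event_id = ev_counter, day = e$day,
        start_minute = e$start, end_minute = e$end, duration = e$duration,
        rest_c_true = rest_c_true, met_during = met_during,
        delta_true = resp$delta_rmssd, direction_true = resp$direction,
        recovery_minutes_true = resp$recovery_minutes,
        truncated = resp$truncated)
    }

    # physical-activity bouts depress vmHRV through the same event-response
    # model, so device-detected bouts show the decrease a wearable records
    # and pooled fits see one generating process across event types
    for (b in bouts) {
      idx_b <- which(act$minute >= b$start & act$minute < b$start + b$len)
      if (length(idx_b) == 0) next
      resp_b <- inject_event_response(rest_ln_slow[b$day],
                                      b$level - config$met_center,
                                      config$beta_reactivity,
                                      config$beta_recovery,
                                      noise_sd = config$reactivity_noise_sd,
                                      person_effect = react_int,
                                      recovery_person_effect = rec_int,
                                      timeout = config$recovery_timeout)
      base_b <- exp(rest_ln_mean + rest_ln_slow[b$day])
      target[idx_b] <- pmax(base_b + resp_b$delta_rmssd, 3)
    }

    # --- RR series realizing the trajectory, one block per waking window ---
    rr_blocks <- lapply(seq_len(config$n_days), function(d) {
      day_idx <- which(act$day == d)
      tg <- target[day_idx]
      tg[!act$worn[day_idx]] <- NA  # no beats while not worn
      # synthesize on worn runs only
      runs <- rle(!is.na(tg))
      pos <- cumsum(c(1, runs$lengths))
      blocks <- list()
      for (j in seq_along(runs$lengths)) {
        if (!runs$values[j]) next
        i0 <- pos[j]; i1 <- pos[j] + runs$lengths[j] - 1
        blk <- synthesize_rr(tg[i0:i1], config$mean_rr,
                             offset_sec = act$minute[day_idx[i0]] * 60)
        blocks[[length(blocks) + 1]] <- blk
      }
      dplyr::bind_rows(blocks)
    })
    rr <- dplyr::bind_rows(rr_blocks)
    if (config$artifact_fraction > 0 && nrow(rr) > 0) {
      n_art <- round(config$artifact_fraction * nrow(rr))
      if (n_art > 0) {
        idx <- sample(nrow(rr), n_art)
        rr$rr[idx] <- rr$rr[idx] *
          sample(c(0.3, 0.45, 1.9, 2.6), n_art, replace = TRUE)
      }
    }
    rr$person_id <- pid

    # --- markers: a tap at each scheduled event's start minute ---
    if (length(ev_truth_p) > 0) {
      evt <- dplyr::bind_rows(ev_truth_p)
      markers <- tibble::tibble(person_id = pid,
                                marker_id = evt$event_id,
                                minute = evt$start_minute,
                                source = "self")
    } else {
      evt <- tibble::tibble()
      markers <- tibble::tibble(person_id = character(), marker_id = integer(),
                                minute = numeric(), source = character())
    }

    # --- diaries: 8/day, 2 h apart, first at 08:00 ---
    diary_rows <- list()
    for (d in seq_len(config$n_days)) {
      times <- (d - 1) * 1440 + seq(8 * 60, by = 120, length.out = 8)
      prev <- c((d - 1) * 1440, times[-length(times)])
      for (k in seq_along(times)) {
        in_win <- if (nrow(evt) > 0)
          which(evt$start_minute > prev[k] & evt$start_minute <= times[k])
        else integer()
        n_rep <- length(in_win)
        flags <- stats::rbinom(length(config$covariate_prevalences), 1,
                               config$covariate_prevalences)
        names(flags) <- names(config$covariate_prevalences)
        base_row <- tibble::tibble(person_id = pid, diary_minute = times[k],
                                   n_events = n_rep,
                                   caffeine = flags[["caffeine"]],
                                   alcohol = flags[["alcohol"]],
                                   nicotine = flags[["nicotine"]],
                                   anticipated_stress = flags[["anticipated_stress"]],
                                   ambient_noise = flags[["ambient_noise"]])
        if (n_rep == 0) {
          base_row$report_id <- NA_integer_
          base_row$reported_start <- NA_real_
          base_row$reported_duration <- NA_real_
          base_row$accident <- FALSE
          diary_rows[[length(diary_rows) + 1]] <- base_row
        } else {
          for (j in in_win) {
            row <- base_row
            row$report_id <- evt$event_id[j]
            row$reported_start <- evt$start_minute[j] +
              round(stats::rnorm(1, 0, config$diary_time_noise_sd))
            row$reported_duration <- max(1, round(
              evt$duration[j] + stats::rnorm(1, 0, config$diary_duration_noise_sd)))
            row$accident <- stats::runif(1) < config$accident_prob
            diary_rows[[length(diary_rows) + 1]] <- row
          }
        }
      }
    }
    diaries <- dplyr::bind_rows(diary_rows)

    # --- person-level table ---
    pss_latent <- stats::rnorm(1, 1.9, 0.7)  # item-scale location
    pss_items <- pmin(4, pmax(0, round(stats::rnorm(10, pss_latent, 0.9))))
    pers_rows[[p]] <- tibble::tibble(
      person_id = pid,
      pss1 = pss_items[1], pss2 = pss_items[2], pss3 = pss_items[3],
      pss4 = pss_items[4], pss5 = pss_items[5], pss6 = pss_items[6],
      pss7 = pss_items[7], pss8 = pss_items[8], pss9 = pss_items[9],
      pss10 = pss_items[10],
      bmi = round(stats::rnorm(1, 23.3, 2.6), 1),
      mvpa_hours = round(pmax(0, stats::rnorm(1, 5.4, 3.1)), 1),
      sex = sample(c("female", "male"), 1, prob = c(0.79, 0.21)),
      age = round(stats::rnorm(1, 23.8, 4.2)),
      first_minute = min(act$minute))
    truth_pers[[p]] <- tibble::tibble(person_id = pid,
                                      rest_ln_mean = rest_ln_mean,
                                      reactivity_intercept = react_int,
                                      recovery_intercept = rec_int)
    act$person_id <- pid
    rr_all[[p]] <- rr
    act_all[[p]] <- act[, c("person_id", "minute", "met", "supine_fraction",
                            "worn")]
    mark_all[[p]] <- markers
    diary_all[[p]] <- diaries
    if (nrow(evt) > 0) truth_ev[[length(truth_ev) + 1]] <- evt
  }

  truth_events <- if (length(truth_ev) > 0) dplyr::bind_rows(truth_ev)
    else tibble::tibble(person_id = character(), event_id = integer(),
                        day = integer(), start_minute = numeric(),
                        end_minute = numeric(), duration = numeric(),
                        rest_c_true = numeric(), met_during = numeric(),
                        delta_true = numeric(), direction_true = integer(),
                        recovery_minutes_true = numeric(),
                        truncated = logical())
  list(
    dataset = list(rr = dplyr::bind_rows(rr_all),
                   activity = dplyr::bind_rows(act_all),
                   markers = dplyr::bind_rows(mark_all),
                   diaries = dplyr::bind_rows(diary_all),
                   persons = dplyr::bind_rows(pers_rows)),
    truth = list(events = truth_events,
                 persons = dplyr::bind_rows(truth_pers),
                 fixed_effects = list(reactivity = config$beta_reactivity,
                                      recovery = config$beta_recovery,
                                      person_intercept_sd = config$person_intercept_sd,
                                      reactivity_noise_sd = config$reactivity_noise_sd,
                                      recovery_person_sd = config$recovery_person_sd)))
}
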