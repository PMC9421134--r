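# Independent oracles and fixture builders used across the suite.

# Brute-force RMSSD straight from a beat list: pool squared differences of
# originally-adjacent valid beats whose two members fall in the same minute,
# over the five minutes [start, start + 4].
oracle_rmssd_from_beats <- function(beat_time, rr, valid, start_minute) {
  d2 <- c()
  for (i in 2:length(rr)) {
    m_prev <- floor(beat_time[i - 1] / 60)
    m_cur <- floor(beat_time[i] / 60)
    if (valid[i - 1] && valid[i] && m_prev == m_cur &&
        m_cur >= start_minute && m_cur <= start_minute + 4)
      d2 <- c(d2, (rr[i] - rr[i - 1])^2)
  }
  if (length(d2) == 0) return(NA_real_)
  sqrt(mean(d2))
}

# Window RMSSD computed definitionally from minute records (used by the
# recovery oracle); mirrors the formula, not the implementation path.
oracle_window_rmssd <- function(minutes, start, min_coverage = 0.8) {
  seg <- minutes[minutes$minute >= start & minutes$minute <= start + 4, ]
  if (nrow(seg) != 5 || any(!seg$worn)) return(NA_real_)
  if (sum(seg$n_succ_pairs) == 0 || sum(seg$n_valid_beats) == 0) return(NA_real_)
  mean_rr_s <- sum(seg$sum_rr_valid) / sum(seg$n_valid_beats) / 1000
  if (sum(seg$n_valid_beats) < min_coverage * 300 / mean_rr_s) return(NA_real_)
  sqrt(sum(seg$sum_sq_succ_diff) / sum(seg$n_succ_pairs))
}

# Exhaustive enumeration over every 1-min-shifted window, replicating the
# censoring rules by direct translation of their definitions.
oracle_recovery <- function(end_minute, resting, direction, minutes,
                            next_marker = Inf, timeout = 120) {
  worn_minutes <- minutes$minute[minutes$worn]
  if (length(worn_minutes) == 0 || end_minute > max(worn_minutes))
    return(list(status = "missing_hrv", k = NA))
  for (k in 0:timeout) {
    if (next_marker < end_minute + k + 5)
      return(list(status = "pileup", k = NA))
    w <- oracle_window_rmssd(minutes, end_minute + k)
    if (is.na(w)) next
    ok <- if (direction == 0) w >= resting else w <= resting
    if (ok) return(list(status = "reached", k = k))
  }
  list(status = "timeout", k = NA)
}

# Random minute-record fixture with occasional unworn minutes.
random_minutes <- function(n = 140, start = 0, unworn_prob = 0.02,
                           rmssd_level = 40) {
  n_beats <- pmax(20L, rpois(n, 72))
  pairs <- pmax(0L, n_beats - sample(1:4, n, replace = TRUE))
  level <- rmssd_level * exp(rnorm(n, 0, 0.2))
  tibble::tibble(
    minute = start + seq_len(n) - 1,
    n_valid_beats = n_beats,
    sum_sq_succ_diff = level^2 * pairs,
    n_succ_pairs = pairs,
    sum_rr_valid = n_beats * 830,
    met = pmax(1, 1.3 + rnorm(n, 0, 0.2)),
    supine_fraction = 0,
    worn = runif(n) > unworn_prob)
}

# Random screened RR fixture spanning `n_min` minutes.
random_rr_fixture <- function(n_min = 7, mean_rr = 850, sd = 30,
                              invalid_prob = 0.05) {
  total <- n_min * 60
  n <- ceiling(total * 1000 / mean_rr)
  rr <- mean_rr + rnorm(n, 0, sd)
  bt <- cumsum(rr) / 1000
  keep <- bt <= total
  tibble::tibble(beat_time = bt[keep], rr = rr[keep],
                 valid = runif(sum(keep)) > invalid_prob)
}

flat_activity <- function(minutes, met = 1.3) {
  tibble::tibble(minute = minutes, met = met, supine_fraction = 0, worn = TRUE)
}
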