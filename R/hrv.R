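#' Screen RR intervals for artifacts
#'
#' Flags implausible inter-beat intervals using an absolute physiological
#' range and a relative-change rule on consecutive intervals: a beat is
#' invalid when its RR interval differs from the previous *valid* beat by
#' more than `max_rel_change` (as a proportion of the previous valid RR),
#' or when it falls outside `rr_range`. The first beat is valid iff it is
#' in range. Ordering is preserved; nothing is removed, only flagged.
#'
#' @param rr Data frame with columns `beat_time` (seconds, strictly
#'   increasing) and `rr` (milliseconds). A `person_id` column, if present,
#'   partitions the screening.
#' @param max_rel_change Maximum allowed relative change between a beat and
#'   the previous valid beat. Default 0.25.
#' @param rr_range Absolute plausibility range in ms. Default c(300, 2000).
#' @return The input with a logical `valid` column (replaced if present).
#' @export
screen_rr <- function(rr, max_rel_change = 0.25, rr_range = c(300, 2000)) {
  stopifnot(is.data.frame(rr), all(c("beat_time", "rr") %in% names(rr)))
  if (nrow(rr) == 0L) stop("empty RR series")
  screen_one <- function(x) {
    n <- length(x)
    valid <- logical(n)
    in_range <- x >= rr_range[1] & x <= rr_range[2]
    prev <- NA_real_
    for (i in seq_len(n)) {
      ok <- in_range[i] &&
        (is.na(prev) || abs(x[i] - prev) / prev <= max_rel_change)
      valid[i] <- ok
      if (ok) prev <- x[i]
    }
    valid
  }
  if ("person_id" %in% names(rr)) {
    rr <- dplyr::group_by(rr, .data$person_id)
    rr <- dplyr::mutate(rr, valid = screen_one(.data$rr))
    dplyr::ungroup(rr)
  } else {
    rr$valid <- screen_one(rr$rr)
    rr
  }
}

#' Aggregate screened RR beats to 60-second resolution
#'
#' Bins beats into whole minutes (`floor(beat_time / 60)`) and accumulates,
#' per minute, the count of valid beats, the sum of squared successive
#' differences over pairs of *adjacent* valid beats falling in the same
#' minute, the pair count, and the summed valid RR (used later for beat
#' coverage). Pairs straddling a minute boundary contribute to neither
#' minute, and a removed (invalid) beat breaks the pair on both sides so
#' artifacts cannot create spurious large differences.
#'
#' @param rr Screened RR series (one person) with `beat_time`, `rr`, `valid`.
#' @param activity Minute-level table with `minute`, `met`,
#'   `supine_fraction`, `worn` covering the recording.
#' @return A tibble of minute records: `minute`, `n_valid_beats`,
#'   `sum_sq_succ_diff`, `n_succ_pairs`, `sum_rr_valid`, `met`,
#'   `supine_fraction`, `worn`. Minutes flagged `worn = FALSE` carry zero
#'   beats regardless of the RR input.
#' @export
aggregate_minutes <- function(rr, activity) {
  stopifnot(all(c("beat_time", "rr", "valid") %in% names(rr)),
            all(c("minute", "met", "supine_fraction", "worn") %in% names(activity)))
  rr_min <- floor(rr$beat_time / 60)
  if (nrow(rr) > 0 &&
      (max(rr_min) < min(activity$minute) || min(rr_min) > max(activity$minute)))
    stop("RR series and activity table cover disjoint time ranges")

  minute <- rr_min
  valid <- rr$valid
  x <- rr$rr
  # adjacent beats, both valid, same minute
  pair_ok <- valid[-length(valid)] & valid[-1] &
    minute[-length(minute)] == minute[-1]
  d2 <- (x[-1] - x[-length(x)])^2
  pair_minute <- minute[-1]

  beats <- tibble::tibble(minute = minute[valid], rr = x[valid])
  beat_agg <- dplyr::summarise(dplyr::group_by(beats, .data$minute),
                               n_valid_beats = dplyr::n(),
                               sum_rr_valid = sum(.data$rr), .groups = "drop")
  pairs <- tibble::tibble(minute = pair_minute[pair_ok], d2 = d2[pair_ok])
  pair_agg <- dplyr::summarise(dplyr::group_by(pairs, .data$minute),
                               sum_sq_succ_diff = sum(.data$d2),
                               n_succ_pairs = dplyr::n(), .groups = "drop")

  out <- dplyr::left_join(tibble::as_tibble(activity), beat_agg, by = "minute")
  out <- dplyr::left_join(out, pair_agg, by = "minute")
  out <- dplyr::mutate(out,
    n_valid_beats = ifelse(is.na(.data$n_valid_beats), 0L, .data$n_valid_beats),
    sum_rr_valid = ifelse(is.na(.data$sum_rr_valid), 0, .data$sum_rr_valid),
    sum_sq_succ_diff = ifelse(is.na(.data$sum_sq_succ_diff), 0, .data$sum_sq_succ_diff),
    n_succ_pairs = ifelse(is.na(.data$n_succ_pairs), 0L, .data$n_succ_pairs))
  # unworn minutes carry no usable beats
  out <- dplyr::mutate(out,
    n_valid_beats = ifelse(.data$worn, .data$n_valid_beats, 0L),
    sum_rr_valid = ifelse(.data$worn, .data$sum_rr_valid, 0),
    sum_sq_succ_diff = ifelse(.data$worn, .data$sum_sq_succ_diff, 0),
    n_succ_pairs = ifelse(.data$worn, .data$n_succ_pairs, 0L))
  dplyr::arrange(out, .data$minute)
}

#' RMSSD over a 5-minute segment of minute records
#'
#' Pools the per-minute successive-difference sums over the five minutes
#' `[start_minute, start_minute + 4]`:
#' \deqn{RMSSD = \sqrt{\sum \mathrm{ssd} / \sum n_{pairs}}.}
#' The segment is undefined (all HRV fields `NA`) when any of its minutes is
#' unworn or absent, when no successive pairs exist, or when the total
#' valid-beat count falls below `min_coverage` of the expected beat count
#' (300 s divided by the segment's mean valid RR). `mean_met` averages MET
#' and `supine_minutes` sums the supine fractions over the five minutes.
#'
#' @param minutes Minute-record table from [aggregate_minutes()].
#' @param start_minute First minute index of the segment.
#' @param min_coverage Minimum fraction of expected beats. Default 0.8.
#' @return One-row tibble: `start_minute`, `length`, `rmssd`, `ln_rmssd`,
#'   `mean_met`, `supine_minutes`, `defined`.
#' @export
segment_rmssd <- function(minutes, start_minute, min_coverage = 0.8) {
  want <- start_minute + 0:4
  seg <- minutes[minutes$minute %in% want, , drop = FALSE]
  undef <- tibble::tibble(start_minute = start_minute, length = 5L,
                          rmssd = NA_real_, ln_rmssd = NA_real_,
                          mean_met = NA_real_, supine_minutes = NA_real_,
                          defined = FALSE)
  if (nrow(seg) != 5L) return(undef)
  if (!identical(sort(seg$minute), as.numeric(sort(want))) &&
      !identical(sort(seg$minute), as.integer(sort(want))))
    stop("segment minutes are not consecutive")
  met <- mean(seg$met)
  sup <- sum(seg$supine_fraction)
  if (any(!seg$worn)) return(undef)
  n_pairs <- sum(seg$n_succ_pairs)
  n_beats <- sum(seg$n_valid_beats)
  if (n_pairs == 0L || n_beats == 0L) {
    undef$mean_met <- met; undef$supine_minutes <- sup
    return(undef)
  }
  mean_rr_s <- (sum(seg$sum_rr_valid) / n_beats) / 1000
  expected <- 300 / mean_rr_s
  if (n_beats < min_coverage * expected) {
    undef$mean_met <- met; undef$supine_minutes <- sup
    return(undef)
  }
  r <- sqrt(sum(seg$sum_sq_succ_diff) / n_pairs)
  tibble::tibble(start_minute = start_minute, length = 5L, rmssd = r,
                 ln_rmssd = ln_rmssd(r), mean_met = met,
                 supine_minutes = sup, defined = TRUE)
}

#' Natural-log transform of RMSSD
#'
#' RMSSD distributions are right-skewed; analyses use lnRMSSD. A zero RMSSD
#' (constant RR, physiologically impossible in real recordings) maps to
#' `NA` rather than `-Inf` and propagates as missing.
#'
#' @param rmssd RMSSD in ms (vectorized).
#' @return Natural log of `rmssd`; `NA` where `rmssd` is 0 or missing.
#' @export
ln_rmssd <- function(rmssd) {
  out <- ifelse(!is.na(rmssd) & rmssd > 0, log(rmssd), NA_real_)
  as.numeric(out)
}
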