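#' Filter stress markers by the four validity rules
#'
#' Applies, per person and in chronological order, the exclusion rules for
#' self-set stress markers: (a) set while the sensor was not worn;
#' (c) flagged in the diaries as set by accident; (d) tied to a reported
#' event lasting under 5 minutes (strict `< 5`); (b) set inside the 5-min
#' reactivity segment `[m+1, m+5]` of the previous *kept* marker. Rules (a),
#' (c) and (d) are evaluated first, then (b) sweeps chronologically over the
#' survivors, so each excluded marker carries exactly one reason.
#'
#' @param markers Tibble with `person_id`, `marker_id`, `minute`, `source`,
#'   and optionally `accident` (logical) and `reported_duration` (minutes,
#'   `NA` when no diary report was matched).
#' @param minutes Minute-record table (or any table with `person_id` where
#'   multi-person, `minute`, `worn`) giving wear state.
#' @return `markers` with `excluded_reason` (`"none"`, `"not_worn"`,
#'   `"accidental"`, `"too_short"`, `"same_segment"`) and logical `kept`.
#' @export
filter_markers <- function(markers, minutes) {
  stopifnot(all(c("person_id", "marker_id", "minute") %in% names(markers)))
  if (!"accident" %in% names(markers)) markers$accident <- FALSE
  if (!"reported_duration" %in% names(markers))
    markers$reported_duration <- NA_real_
  worn_lookup <- function(pid, m) {
    act <- if ("person_id" %in% names(minutes))
      minutes[minutes$person_id == pid, ] else minutes
    row <- act[act$minute == m, , drop = FALSE]
    nrow(row) == 1L && isTRUE(row$worn[1])
  }
  out <- dplyr::arrange(tibble::as_tibble(markers), .data$person_id, .data$minute)
  reason <- rep("none", nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!worn_lookup(out$person_id[i], out$minute[i])) {
      reason[i] <- "not_worn"
    } else if (isTRUE(out$accident[i])) {
      reason[i] <- "accidental"
    } else if (!is.na(out$reported_duration[i]) && out$reported_duration[i] < 5) {
      reason[i] <- "too_short"
    }
  }
  # rule (b): chronological sweep over survivors, per person
  for (pid in unique(out$person_id)) {
    idx <- which(out$person_id == pid & reason == "none")
    prev_kept <- NA_real_
    for (i in idx) {
      m <- out$minute[i]
      if (!is.na(prev_kept) && m >= prev_kept + 1 && m <= prev_kept + 5) {
        reason[i] <- "same_segment"
      } else {
        prev_kept <- m
      }
    }
  }
  out$excluded_reason <- reason
  out$kept <- reason == "none"
  out
}

#' Detect physically stressful events from minute-level MET
#'
#' Locates maximal runs of worn minutes with `met >= threshold` lasting at
#' least `min_duration` minutes and places a device marker at each run's
#' first minute. Runs overlapping the reactivity window `[m+1, m+5]` of a
#' kept self-marker produce no additional marker (the event is already
#' represented).
#'
#' @param minutes Minute-record table for one person (`minute`, `met`,
#'   `worn`).
#' @param threshold MET cut-off for moderate activity. Default 3.
#' @param min_duration Minimum run length in minutes. Default 5.
#' @param kept_self_minutes Minute indices of kept self-markers (optional).
#' @return Tibble of device markers: `minute`, `run_length`, `source`.
#' @export
detect_physical_events <- function(minutes, threshold = 3, min_duration = 5,
                                   kept_self_minutes = integer()) {
  stopifnot(all(c("minute", "met", "worn") %in% names(minutes)))
  minutes <- dplyr::arrange(minutes, .data$minute)
  hi <- !is.na(minutes$met) & minutes$met >= threshold & minutes$worn
  if (!any(hi)) {
    return(tibble::tibble(minute = integer(), run_length = integer(),
                          source = character()))
  }
  r <- rle(hi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  run_start_min <- minutes$minute[starts[keep]]
  run_len <- r$lengths[keep]
  if (length(kept_self_minutes) > 0 && length(run_start_min) > 0) {
    overlaps <- vapply(seq_along(run_start_min), function(j) {
      run <- seq(run_start_min[j], length.out = run_len[j])
      any(vapply(kept_self_minutes,
                 function(m) any(run >= m + 1 & run <= m + 5), logical(1)))
    }, logical(1))
    run_start_min <- run_start_min[!overlaps]
    run_len <- run_len[!overlaps]
  }
  tibble::tibble(minute = as.integer(run_start_min),
                 run_length = as.integer(run_len),
                 source = rep("device", length(run_start_min)))
}

#' Build an event record around a kept marker
#'
#' The resting segment covers the five minutes before the marker minute
#' (`[m-5, m-1]`) and the reactivity segment the five minutes after it
#' (`[m+1, m+5]`); the marker minute itself is transitional and belongs to
#' neither. The reactivity outcome is the raw difference
#' `delta_rmssd = reactivity - resting` (ms) and the direction dummy is 1
#' for an increase, 0 for a decrease; an exact tie (possible only in toy
#' data) is coded 0 with a warning. The record is flagged missing when
#' either segment's RMSSD is undefined, including markers within 5 minutes
#' of recording start.
#'
#' @param marker_minute Minute index of a kept marker.
#' @param minutes Minute-record table for the marker's person.
#' @param min_coverage Passed to [segment_rmssd()].
#' @return One-row tibble: segment summaries (`rest_*`, `react_*`),
#'   `delta_rmssd`, `direction`, `complete`.
#' @export
build_event_record <- function(marker_minute, minutes, min_coverage = 0.8) {
  first_min <- min(minutes$minute)
  rest <- if (marker_minute - 5 >= first_min)
    segment_rmssd(minutes, marker_minute - 5, min_coverage)
  else segment_rmssd(minutes[0, ], marker_minute - 5, min_coverage)
  react <- segment_rmssd(minutes, marker_minute + 1, min_coverage)
  complete <- isTRUE(rest$defined) && isTRUE(react$defined)
  delta <- if (complete) react$rmssd - rest$rmssd else NA_real_
  direction <- NA_integer_
  if (complete) {
    if (delta == 0) {
      warning("tie: reactivity equals resting RMSSD; direction coded 0")
      direction <- 0L
    } else direction <- as.integer(delta > 0)
  }
  tibble::tibble(
    marker_minute = marker_minute,
    rest_rmssd = rest$rmssd, rest_ln_rmssd = rest$ln_rmssd,
    rest_met = rest$mean_met, rest_supine = rest$supine_minutes,
    react_rmssd = react$rmssd, react_ln_rmssd = react$ln_rmssd,
    react_met = react$mean_met, react_supine = react$supine_minutes,
    delta_rmssd = delta, direction = direction, complete = complete)
}
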