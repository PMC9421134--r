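#' Match diary event reports to kept stress markers
#'
#' Processes a person's reports chronologically and assigns each to the
#' still-unmatched kept marker closest in time to the reported event start,
#' provided the distance is at most `window` minutes (inclusive); otherwise
#' the report is unmatched. Equidistant candidates resolve to the earlier
#' marker. Matching is one-to-one: a marker absorbed by one report is
#' unavailable to later reports.
#'
#' @param reports Tibble with `report_id`, `reported_start` (study minute),
#'   `reported_duration` (minutes), ordered or orderable by `reported_start`.
#' @param markers Tibble of kept markers with `marker_id`, `minute`.
#' @param window Maximum |marker - reported start| in minutes. Default 120.
#' @return `reports` with `marker_id` (`NA` when unmatched), `marker_minute`
#'   and `matched`.
#' @export
match_reports <- function(reports, markers, window = 120) {
  reports <- dplyr::arrange(tibble::as_tibble(reports), .data$reported_start)
  avail <- markers
  out_marker <- rep(NA_integer_, nrow(reports))
  out_minute <- rep(NA_real_, nrow(reports))
  for (i in seq_len(nrow(reports))) {
    if (nrow(avail) == 0) break
    d <- abs(avail$minute - reports$reported_start[i])
    j <- which(d == min(d))
    if (length(j) > 1) j <- j[which.min(avail$minute[j])]  # earlier marker
    if (d[j] <= window) {
      out_marker[i] <- avail$marker_id[j]
      out_minute[i] <- avail$minute[j]
      avail <- avail[-j, , drop = FALSE]
    }
  }
  reports$marker_id <- out_marker
  reports$marker_minute <- out_minute
  reports$matched <- !is.na(out_marker)
  reports
}

#' Locate the end of a stressful event
#'
#' The recovery phase starts where the event ends: the self-reported
#' duration added to the marker minute. Fractional durations are rounded up
#' to the 60-s grid.
#'
#' @param marker_minute Minute index of the matched marker.
#' @param reported_duration Self-reported duration in minutes.
#' @return End minute (integer), or `NA` when the duration is missing.
#' @export
locate_event_end <- function(marker_minute, reported_duration) {
  if (is.na(reported_duration)) return(NA_real_)
  marker_minute + ceiling(reported_duration)
}

#' Compute recovery time with sliding 5-minute windows
#'
#' Scans 5-min windows starting at the event end and shifted by 1 min each
#' step: for offsets k = 0, 1, 2, ... the window `[end+k, end+k+4]` is
#' evaluated and recovery is reached at the first k whose RMSSD crosses the
#' resting level in the restorative direction — at or above resting for
#' decrease events (`direction = 0`), at or below resting for increase
#' events (`direction = 1`); equality counts as recovered. Censoring:
#' `pileup` when the next marker occurs before the current window completes
#' (`next_marker_minute < end+k+5`), `timeout` when k would exceed the
#' 120-min limit, `missing_hrv` when the event end lies beyond the
#' recording. Windows with undefined RMSSD are skipped (k advances) and
#' counted.
#'
#' @param end_minute Event end minute from [locate_event_end()].
#' @param resting_rmssd Resting-segment RMSSD (ms).
#' @param direction Reactivity direction dummy (0 decrease, 1 increase).
#' @param minutes Minute-record table for the person.
#' @param next_marker_minute Minute of the person's next kept marker
#'   (`Inf` when none).
#' @param timeout Maximum window offset k in minutes. Default 120.
#' @param min_coverage Passed to [segment_rmssd()].
#' @return One-row tibble: `recovery_minutes` (`NA` unless reached),
#'   `status` (`reached`/`pileup`/`timeout`/`missing_hrv`),
#'   `n_windows_checked`, and `recovery_met`/`recovery_supine` (means over
#'   `[end, end+k+4]` when reached, else `NA`).
#' @export
compute_recovery <- function(end_minute, resting_rmssd, direction, minutes,
                             next_marker_minute = Inf, timeout = 120,
                             min_coverage = 0.8) {
  stopifnot(direction %in% c(0, 1), !is.na(resting_rmssd))
  res <- function(status, k = NA_real_, n = 0L, met = NA_real_, sup = NA_real_)
    tibble::tibble(recovery_minutes = as.numeric(k), status = status,
                   n_windows_checked = n, recovery_met = met,
                   recovery_supine = sup)
  if (is.na(end_minute)) return(res("missing_hrv"))
  worn_max <- suppressWarnings(max(minutes$minute[minutes$worn]))
  if (!is.finite(worn_max) || end_minute > worn_max)
    return(res("missing_hrv"))
  n_checked <- 0L
  for (k in 0:timeout) {
    if (next_marker_minute < end_minute + k + 5)
      return(res("pileup", n = n_checked))
    seg <- segment_rmssd(minutes, end_minute + k, min_coverage)
    n_checked <- n_checked + 1L
    if (!isTRUE(seg$defined)) next
    hit <- if (direction == 0) seg$rmssd >= resting_rmssd
           else seg$rmssd <= resting_rmssd
    if (hit) {
      span <- minutes[minutes$minute >= end_minute &
                      minutes$minute <= end_minute + k + 4, , drop = FALSE]
      return(res("reached", k = k, n = n_checked,
                 met = mean(span$met, na.rm = TRUE),
                 sup = mean(span$supine_fraction, na.rm = TRUE)))
    }
  }
  res("timeout", n = n_checked)
}
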