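#' Code time-windowed event covariate flags from bihourly diaries
#'
#' Each diary prompt reports on the preceding 2 hours. A substance or
#' anticipation flag is set for an event when any positive diary report's
#' look-back window `[diary - 120, diary]` overlaps the event's +/- 2 h
#' window `[event - 120, event + 120]`; for ambient noise only the
#' preceding window `[event - 120, event]` counts. All intervals are closed.
#'
#' @param event_minute Study minute of the event (marker minute).
#' @param diaries Tibble for the person: `diary_minute` plus 0/1 columns
#'   `caffeine`, `alcohol`, `nicotine`, `anticipated_stress`,
#'   `ambient_noise`.
#' @return One-row tibble of 0/1 flags.
#' @export
code_event_flags <- function(event_minute, diaries) {
  flags <- c("caffeine", "alcohol", "nicotine", "anticipated_stress",
             "ambient_noise")
  stopifnot(all(c("diary_minute", flags) %in% names(diaries)))
  lo <- diaries$diary_minute - 120
  hi <- diaries$diary_minute
  overlaps <- function(win_lo, win_hi) lo <= win_hi & hi >= win_lo
  both <- overlaps(event_minute - 120, event_minute + 120)
  pre <- overlaps(event_minute - 120, event_minute)
  out <- lapply(flags, function(f) {
    rel <- if (f == "ambient_noise") pre else both
    as.integer(any(diaries[[f]] == 1 & rel))
  })
  names(out) <- flags
  tibble::as_tibble(out)
}

#' Winsorize at three standard deviations
#'
#' Replaces values diverging more than 3 SD from the mean with the value
#' exactly 3 SD from the mean. Mean and SD come from the series before any
#' replacement, and the rule is applied once (a second pass is a no-op on
#' the same moments). Constant series are returned unchanged.
#'
#' @param x Numeric vector; `NA`s pass through.
#' @param n_sd Number of SDs. Default 3.
#' @return `x` with outliers clipped to `mean +/- n_sd * sd`.
#' @export
winsorize_3sd <- function(x, n_sd = 3) {
  fin <- is.finite(x)
  if (sum(fin) < 2) return(x)
  m <- mean(x[fin]); s <- stats::sd(x[fin])
  if (!is.finite(s) || s == 0) return(x)
  pmin(pmax(x, m - n_sd * s), m + n_sd * s)
}

#' Center values on a group or grand mean
#'
#' Group-mean centering (grouping given) subtracts each group's own mean so
#' coefficients reflect within-person deviations; grand-mean centering
#' (grouping `NULL`) subtracts the overall mean. Group means are attached
#' as the `"means"` attribute.
#'
#' @param x Numeric vector.
#' @param group Optional grouping vector (e.g. person id).
#' @return Centered vector with attribute `means`.
#' @export
center_values <- function(x, group = NULL) {
  if (is.null(group)) {
    m <- mean(x, na.rm = TRUE)
    out <- x - m
    attr(out, "means") <- m
    return(out)
  }
  gm <- tapply(x, group, mean, na.rm = TRUE)
  out <- x - as.numeric(gm[as.character(group)])
  attr(out, "means") <- gm
  out
}

#' Remove physiologically improbable MET values
#'
#' Values above 79.8 MET (three times the mean functional capacity observed
#' in exercise testing) are considered device artifacts and set to missing.
#' The threshold is exclusive: exactly 79.8 is kept.
#'
#' @param met Numeric MET values.
#' @param max_met Exclusive upper bound. Default 79.8.
#' @return `met` with improbable values replaced by `NA`.
#' @export
screen_met <- function(met, max_met = 79.8) {
  met[!is.na(met) & met > max_met] <- NA_real_
  met
}

#' Score the 10-item Perceived Stress Scale
#'
#' Items are answered 0-4; the four positively worded items (4, 5, 7, 8 in
#' the standard ordering) are reverse-scored (`4 - response`) and all ten
#' are summed to a 0-40 total. Any missing item makes the total missing.
#'
#' @param items Numeric matrix or data frame, one row per person, 10
#'   columns in standard item order.
#' @return Numeric vector of totals.
#' @export
score_pss10 <- function(items) {
  items <- as.matrix(items)
  stopifnot(ncol(items) == 10)
  if (any(items < 0 | items > 4, na.rm = TRUE))
    stop("PSS-10 responses must lie in 0-4")
  rev_idx <- c(4, 5, 7, 8)
  items[, rev_idx] <- 4 - items[, rev_idx]
  rowSums(items)
}

#' Standardize to z-scores
#'
#' @param x Numeric vector.
#' @return `(x - mean) / sd` over non-missing values.
#' @export
standardize <- function(x) {
  (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
}

#' Assemble model-ready reactivity and recovery tables
#'
#' Joins event records, recovery results, diary-coded flags and
#' person-level covariates into the two analysis tables, applying the
#' event-level transforms in a fixed order: MET screening (> 79.8 removed),
#' log-transform of resting RMSSD, 3-SD winsorization of each continuous
#' measure, group-mean centering of resting lnRMSSD within person,
#' grand-mean centering of the continuous covariates (chronic stress enters
#' already standardized), and listwise deletion of incomplete rows.
#' `time_in_study` is days since the person's first recorded minute.
#'
#' @param events Event table: one row per kept marker with the
#'   [build_event_record()] columns plus `person_id`, `event_id`,
#'   `marker_minute`, `source`, and flag columns from [code_event_flags()].
#' @param recoveries Recovery table: `event_id`, `recovery_minutes`,
#'   `status`, `recovery_met`, `recovery_supine` (may be empty).
#' @param persons Person table: `person_id`, `bmi`, `mvpa_hours`,
#'   `chronic_stress_z`, `first_minute`.
#' @return List with `reactivity` and `recovery` tibbles.
#' @export
assemble_analysis_tables <- function(events, recoveries, persons) {
  ev <- tibble::as_tibble(events)
  ev$rest_met <- screen_met(ev$rest_met)
  ev$react_met <- screen_met(ev$react_met)
  ev <- dplyr::left_join(ev, persons, by = "person_id")
  ev$time_in_study <- (ev$marker_minute - ev$first_minute) / 1440

  for (v in c("delta_rmssd", "rest_ln_rmssd", "rest_met", "react_met",
              "rest_supine", "react_supine"))
    ev[[v]] <- winsorize_3sd(ev[[v]])
  ev$rest_c <- as.numeric(center_values(ev$rest_ln_rmssd, ev$person_id))
  for (v in c("rest_met", "react_met", "rest_supine", "react_supine",
              "time_in_study", "mvpa_hours", "bmi"))
    ev[[paste0(v, "_c")]] <- as.numeric(center_values(ev[[v]]))

  react_cols <- c("person_id", "event_id", "source", "delta_rmssd", "rest_c",
                  "rest_met_c", "react_met_c", "rest_supine_c",
                  "react_supine_c", "time_in_study_c", "caffeine", "alcohol",
                  "anticipated_stress", "ambient_noise", "mvpa_hours_c",
                  "bmi_c", "chronic_stress_z")
  react_cols <- intersect(react_cols, names(ev))
  reactivity <- ev[, react_cols, drop = FALSE]
  reactivity <- reactivity[stats::complete.cases(reactivity), , drop = FALSE]
  if (nrow(reactivity) == 0) stop("reactivity table empty after listwise deletion")

  if (nrow(recoveries) > 0) {
    rec <- dplyr::inner_join(tibble::as_tibble(recoveries),
                             ev[, c("person_id", "event_id", "rest_c",
                                    "direction", "rest_met_c",
                                    "time_in_study_c")],
                             by = c("person_id", "event_id"))
    rec$recovery_met <- screen_met(rec$recovery_met)
    rec$recovery_met_c <- as.numeric(center_values(winsorize_3sd(rec$recovery_met)))
    keep <- c("person_id", "event_id", "recovery_minutes", "status", "rest_c",
              "direction", "rest_met_c", "recovery_met_c", "time_in_study_c")
    rec <- rec[, intersect(keep, names(rec)), drop = FALSE]
    complete_pred <- stats::complete.cases(
      rec[, setdiff(names(rec), c("recovery_minutes", "recovery_met_c")), drop = FALSE])
    reached_ok <- rec$status != "reached" |
      (!is.na(rec$recovery_minutes) & !is.na(rec$recovery_met_c))
    rec <- rec[complete_pred & reached_ok, , drop = FALSE]
  } else {
    rec <- tibble::tibble(person_id = character(), event_id = integer(),
                          recovery_minutes = numeric(), status = character(),
                          rest_c = numeric(), direction = integer(),
                          rest_met_c = numeric(), recovery_met_c = numeric(),
                          time_in_study_c = numeric())
  }
  list(reactivity = reactivity, recovery = rec)
}
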