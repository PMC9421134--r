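#' Analysis configuration
#'
#' Centralizes the pipeline constants: artifact-screening parameters,
#' segment coverage, the MET threshold (3 MET) and minimum duration (5 min)
#' for device-detected physically stressful events, the diary-match window
#' (2 h) and the recovery timeout (120 min).
#'
#' @param max_rel_change,rr_range,min_coverage See [screen_rr()] and
#'   [segment_rmssd()].
#' @param met_threshold,met_min_duration See [detect_physical_events()].
#' @param match_window See [match_reports()].
#' @param recovery_timeout See [compute_recovery()].
#' @param include_device_events Add MET-detected events to the reactivity
#'   table. Default TRUE.
#' @param fit_models Fit the two mixed models at the end. Default TRUE.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(max_rel_change = 0.25, rr_range = c(300, 2000),
                         min_coverage = 0.8, met_threshold = 3,
                         met_min_duration = 5, match_window = 120,
                         recovery_timeout = 120,
                         include_device_events = TRUE, fit_models = TRUE) {
  cfg <- as.list(environment())
  stopifnot(max_rel_change > 0, min_coverage > 0, met_threshold > 0,
            met_min_duration > 0, match_window > 0, recovery_timeout > 0)
  structure(cfg, class = "study_config")
}

#' Process one person's recording into events and recoveries
#'
#' Runs the full per-person chain: artifact screening, 60-s aggregation,
#' diary-to-marker annotation (accident flags and reported durations),
#' the four marker validity rules, MET-based device event detection, event
#' record construction, covariate flag coding, and sliding-window recovery
#' computation for diary-matched self-marked events.
#'
#' @param rr,activity,markers,diaries Person-level slices of the cohort
#'   tables (see [simulate_cohort()]).
#' @param config A [study_config()].
#' @return List of tibbles: `minutes`, `markers` (with exclusion reasons),
#'   `events`, `recoveries`.
#' @export
process_person <- function(rr, activity, markers, diaries, config = study_config()) {
  rr <- screen_rr(rr, config$max_rel_change, config$rr_range)
  minutes <- aggregate_minutes(rr, activity)

  reports <- diaries[!is.na(diaries$reported_start), , drop = FALSE]
  if (nrow(markers) > 0) {
    ann <- if (nrow(reports) > 0)
      match_reports(reports, markers, config$match_window)
    else reports
    markers$accident <- FALSE
    markers$reported_duration <- NA_real_
    if (nrow(reports) > 0) {
      hit <- ann[ann$matched, , drop = FALSE]
      idx <- match(hit$marker_id, markers$marker_id)
      markers$accident[idx] <- hit$accident
      markers$reported_duration[idx] <- hit$reported_duration
    }
    markers <- filter_markers(markers, minutes)
  } else {
    markers$excluded_reason <- character()
    markers$kept <- logical()
  }
  kept_self <- markers[markers$kept, , drop = FALSE]

  device <- detect_physical_events(minutes, config$met_threshold,
                                   config$met_min_duration,
                                   kept_self_minutes = kept_self$minute)
  next_id <- if (nrow(markers) > 0) max(markers$marker_id) else 0L
  if (nrow(device) > 0 && config$include_device_events) {
    device$marker_id <- next_id + seq_len(nrow(device))
    device$person_id <- rr$person_id[1]
  } else {
    device <- device[0, ]
  }

  all_kept <- dplyr::bind_rows(
    kept_self[, c("person_id", "marker_id", "minute", "source")],
    if (nrow(device) > 0)
      device[, c("person_id", "marker_id", "minute", "source")])

  events <- if (nrow(all_kept) > 0) {
    dplyr::bind_rows(lapply(seq_len(nrow(all_kept)), function(i) {
      rec <- build_event_record(all_kept$minute[i], minutes,
                                config$min_coverage)
      flags <- code_event_flags(all_kept$minute[i], diaries)
      dplyr::bind_cols(
        tibble::tibble(person_id = all_kept$person_id[i],
                       event_id = all_kept$marker_id[i],
                       source = all_kept$source[i]),
        rec, flags)
    }))
  } else tibble::tibble()

  # recovery: diary reports re-matched against kept self-markers only
  recoveries <- tibble::tibble()
  if (nrow(kept_self) > 0 && nrow(reports) > 0) {
    rematch <- match_reports(reports, kept_self, config$match_window)
    rematch <- rematch[rematch$matched, , drop = FALSE]
    recoveries <- dplyr::bind_rows(lapply(seq_len(nrow(rematch)), function(i) {
      mid <- rematch$marker_id[i]
      erow <- events[events$event_id == mid, , drop = FALSE]
      base <- tibble::tibble(person_id = rematch$person_id[i], event_id = mid)
      if (nrow(erow) != 1 || !isTRUE(erow$complete))
        return(dplyr::bind_cols(base, tibble::tibble(
          recovery_minutes = NA_real_, status = "missing_hrv",
          n_windows_checked = 0L, recovery_met = NA_real_,
          recovery_supine = NA_real_)))
      end <- locate_event_end(rematch$marker_minute[i],
                              rematch$reported_duration[i])
      later <- all_kept$minute[all_kept$minute > rematch$marker_minute[i]]
      nxt <- if (length(later) > 0) min(later) else Inf
      dplyr::bind_cols(base, compute_recovery(
        end, erow$rest_rmssd, erow$direction, minutes,
        next_marker_minute = nxt, timeout = config$recovery_timeout,
        min_coverage = config$min_coverage))
    }))
  }
  list(minutes = minutes, markers = markers, events = events,
       recoveries = recoveries)
}

#' Run the full analysis pipeline on a cohort
#'
#' Applies [process_person()] to every person, assembles the two
#' model-ready tables, optionally fits the two mixed models, and (when
#' `out_dir` is given) writes the exclusion log, event, recovery and
#' analysis tables, fit summaries, and a run manifest recording per-stage
#' counts and an overall md5 hash. Reruns on the same dataset and
#' configuration produce byte-identical manifests.
#'
#' @param dataset Cohort list (`rr`, `activity`, `markers`, `diaries`,
#'   `persons`) as from [simulate_cohort()] or [read_cohort()].
#' @param config A [study_config()].
#' @param out_dir Optional output directory.
#' @return List: `events`, `markers`, `recoveries`, `tables`
#'   (reactivity/recovery), `fits` (when fitted), `manifest`.
#' @export
run_pipeline <- function(dataset, config = study_config(), out_dir = NULL) {
  pids <- unique(dataset$persons$person_id)
  per <- lapply(pids, function(pid) {
    tryCatch(
      process_person(dataset$rr[dataset$rr$person_id == pid, ],
                     dataset$activity[dataset$activity$person_id == pid, ],
                     dataset$markers[dataset$markers$person_id == pid, ],
                     dataset$diaries[dataset$diaries$person_id == pid, ],
                     config),
      error = function(e) stop("stage 'process_person' failed for ", pid,
                               ": ", conditionMessage(e)))
  })
  markers <- dplyr::bind_rows(lapply(per, `[[`, "markers"))
  events <- dplyr::bind_rows(lapply(per, `[[`, "events"))
  recoveries <- dplyr::bind_rows(lapply(per, `[[`, "recoveries"))

  persons <- dataset$persons
  pss_cols <- paste0("pss", 1:10)
  if (all(pss_cols %in% names(persons))) {
    persons$pss10_total <- score_pss10(persons[, pss_cols])
    z <- standardize(persons$pss10_total)
    # a degenerate (constant) chronic-stress sample carries no information:
    # code everyone at the mean rather than losing the cohort listwise
    persons$chronic_stress_z <- ifelse(is.finite(z), z, 0)
  }
  keep_cols <- intersect(c("person_id", "bmi", "mvpa_hours",
                           "chronic_stress_z", "first_minute"),
                         names(persons))
  tables <- tryCatch(
    assemble_analysis_tables(events[isTRUE_vec(events$complete), ],
                             recoveries, persons[, keep_cols]),
    error = function(e) stop("stage 'assemble' failed: ",
                             conditionMessage(e)))

  fits <- NULL
  if (config$fit_models) {
    fits <- list(
      reactivity = tryCatch(fit_reactivity(tables$reactivity),
                            error = function(e) conditionMessage(e)),
      recovery = tryCatch(fit_recovery(tables$recovery),
                          error = function(e) conditionMessage(e)))
  }

  manifest <- c(
    sprintf("persons: %d", length(pids)),
    sprintf("markers_set: %d", nrow(markers)),
    sprintf("markers_excluded_not_worn: %d",
            sum(markers$excluded_reason == "not_worn")),
    sprintf("markers_excluded_same_segment: %d",
            sum(markers$excluded_reason == "same_segment")),
    sprintf("markers_excluded_accidental: %d",
            sum(markers$excluded_reason == "accidental")),
    sprintf("markers_excluded_too_short: %d",
            sum(markers$excluded_reason == "too_short")),
    sprintf("markers_kept: %d", sum(markers$kept)),
    sprintf("device_events: %d", sum(events$source == "device")),
    sprintf("events_complete: %d", sum(isTRUE_vec(events$complete))),
    sprintf("recoveries_computed: %d", nrow(recoveries)),
    sprintf("recoveries_reached: %d", sum(recoveries$status == "reached")),
    sprintf("recoveries_pileup: %d", sum(recoveries$status == "pileup")),
    sprintf("recoveries_timeout: %d", sum(recoveries$status == "timeout")),
    sprintf("reactivity_rows: %d", nrow(tables$reactivity)),
    sprintf("recovery_rows_reached: %d",
            sum(tables$recovery$status == "reached")))

  out <- list(markers = markers, events = events, recoveries = recoveries,
              tables = tables, fits = fits, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(markers, file.path(out_dir, "exclusion_log.csv"))
    readr::write_csv(events, file.path(out_dir, "events.csv"))
    readr::write_csv(recoveries, file.path(out_dir, "recoveries.csv"))
    readr::write_csv(tables$reactivity,
                     file.path(out_dir, "reactivity_table.csv"))
    readr::write_csv(tables$recovery, file.path(out_dir, "recovery_table.csv"))
    if (!is.null(fits)) {
      for (nm in names(fits)) {
        if (inherits(fits[[nm]], "hrv_fit")) {
          s <- summarize_fit(fits[[nm]])
          readr::write_csv(s$fixed, file.path(out_dir, paste0("fit_", nm, ".csv")))
        } else {
          writeLines(paste("fit failed:", fits[[nm]]),
                     file.path(out_dir, paste0("fit_", nm, "_error.txt")))
        }
      }
    }
    manifest_path <- file.path(out_dir, "manifest.txt")
    writeLines(manifest, manifest_path)
    out$manifest_hash <- unname(tools::md5sum(manifest_path))
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write / read a cohort as delimited text tables
#'
#' Plain comma-separated UTF-8 files (`rr.csv`, `activity.csv`,
#' `markers.csv`, `diaries.csv`, `persons.csv`), lossless at full double
#' precision. [read_cohort()] validates the schema and basic invariants
#' (required columns, positive RR, increasing beat times per person) and
#' reports offenders with row numbers.
#'
#' @param dataset Cohort list as from [simulate_cohort()].
#' @param dir Directory to write to / read from.
#' @return `write_cohort` the directory invisibly; `read_cohort` the
#'   cohort list.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("rr", "activity", "markers", "diaries", "persons"))
    readr::write_csv(dataset[[nm]], file.path(dir, paste0(nm, ".csv")))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  need <- list(
    rr = c("person_id", "beat_time", "rr"),
    activity = c("person_id", "minute", "met", "supine_fraction", "worn"),
    markers = c("person_id", "marker_id", "minute", "source"),
    diaries = c("person_id", "diary_minute"),
    persons = c("person_id"))
  out <- list()
  for (nm in names(need)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing table file: ", path)
    tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    missing_cols <- setdiff(need[[nm]], names(tbl))
    if (length(missing_cols) > 0)
      stop(nm, ".csv: missing columns ", paste(missing_cols, collapse = ", "))
    out[[nm]] <- tbl
  }
  bad_rr <- which(is.na(out$rr$rr) | out$rr$rr <= 0)
  if (length(bad_rr) > 0)
    stop("rr.csv: non-positive RR at rows ",
         paste(utils::head(bad_rr, 5), collapse = ", "))
  for (pid in unique(out$rr$person_id)) {
    bt <- out$rr$beat_time[out$rr$person_id == pid]
    if (is.unsorted(bt, strictly = TRUE))
      stop("rr.csv: beat times not strictly increasing for ", pid)
  }
  out
}
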