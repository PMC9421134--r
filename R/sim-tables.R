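#' Simulate a model-ready reactivity analysis table
#'
#' Draws an event-level table straight from the reactivity data-generating
#' model — centered resting lnRMSSD, reactivity MET (a light/moderate
#' mixture spanning the self-marked and device-detected range), nuisance
#' covariates with zero true effect, a Gaussian person intercept and
#' residual — for parameter-recovery studies of [fit_reactivity()] without
#' the signal-level machinery.
#'
#' @param n_persons Persons. Default 60.
#' @param events_per_person Events per person. Default 10.
#' @param beta Named true coefficients (`intercept`, `resting`, `met`,
#'   `interaction`), ms scale.
#' @param person_sd SD of the person random intercept (ms). Default 6.07.
#' @param resid_sd Residual SD (ms). Default 12.16.
#' @param rest_sd SD of centered resting lnRMSSD draws. Default 0.4.
#' @return Tibble with the columns [fit_reactivity()] expects.
#' @export
simulate_reactivity_table <- function(n_persons = 60, events_per_person = 10,
                                      beta = c(intercept = -7.06,
                                               resting = -14.06,
                                               met = -3.55,
                                               interaction = -3.85),
                                      person_sd = 6.07, resid_sd = 12.16,
                                      rest_sd = 0.4) {
  n <- n_persons * events_per_person
  pid <- rep(sprintf("P%03d", seq_len(n_persons)), each = events_per_person)
  u <- rep(stats::rnorm(n_persons, 0, person_sd), each = events_per_person)
  rest_c <- stats::rnorm(n, 0, rest_sd)
  # mixture: mostly low-MET self-marked events plus moderate device events
  phys <- stats::runif(n) < 0.4
  met <- ifelse(phys, stats::runif(n, 3, 7), stats::runif(n, 1, 2.5))
  met_c <- met - mean(met)
  y <- beta[["intercept"]] + u + beta[["resting"]] * rest_c +
    beta[["met"]] * met_c + beta[["interaction"]] * rest_c * met_c +
    stats::rnorm(n, 0, resid_sd)
  tibble::tibble(
    person_id = pid, event_id = seq_len(n), delta_rmssd = y,
    rest_c = rest_c, react_met_c = met_c,
    rest_met_c = stats::rnorm(n, 0, 0.7),
    rest_supine_c = stats::rnorm(n, 0, 0.5),
    react_supine_c = stats::rnorm(n, 0, 0.5),
    time_in_study_c = stats::runif(n, -2, 2),
    caffeine = stats::rbinom(n, 1, 0.27),
    alcohol = stats::rbinom(n, 1, 0.04),
    anticipated_stress = stats::rbinom(n, 1, 0.27),
    ambient_noise = stats::rbinom(n, 1, 0.08),
    mvpa_hours_c = stats::rnorm(n, 0, 3.1),
    bmi_c = stats::rnorm(n, 0, 2.6),
    chronic_stress_z = stats::rnorm(n))
}

#' Simulate a model-ready recovery analysis table
#'
#' Draws recovery minutes from the Poisson log-linear model with a person
#' random intercept; counts above `timeout` are flagged `"timeout"` rather
#' than resampled, matching the analysis-side censoring semantics.
#'
#' @param n_persons Persons. Default 60.
#' @param events_per_person Events per person. Default 10.
#' @param beta Named true log-rate coefficients (`intercept`, `resting`,
#'   `direction`, `interaction`).
#' @param person_sd SD of the person log-rate intercept. Default 0.5
#'   (keeps the simulated timeout fraction near the ~7% seen in ambulatory
#'   cohorts).
#' @param rest_sd SD of centered resting lnRMSSD. Default 0.4.
#' @param timeout Censoring limit in minutes. Default 120.
#' @return Tibble with the columns [fit_recovery()] expects, including
#'   `status`.
#' @export
simulate_recovery_table <- function(n_persons = 60, events_per_person = 10,
                                    beta = c(intercept = log(8.72),
                                             resting = log(4.30),
                                             direction = log(0.88),
                                             interaction = log(0.24)),
                                    person_sd = 0.5, rest_sd = 0.4,
                                    timeout = 120) {
  n <- n_persons * events_per_person
  pid <- rep(sprintf("P%03d", seq_len(n_persons)), each = events_per_person)
  u <- rep(stats::rnorm(n_persons, 0, person_sd), each = events_per_person)
  rest_c <- stats::rnorm(n, 0, rest_sd)
  direction <- stats::rbinom(n, 1, 0.5)
  log_mu <- beta[["intercept"]] + u + beta[["resting"]] * rest_c +
    beta[["direction"]] * direction +
    beta[["interaction"]] * rest_c * direction
  y <- stats::rpois(n, exp(log_mu))
  tibble::tibble(
    person_id = pid, event_id = seq_len(n), recovery_minutes = y,
    status = ifelse(y > timeout, "timeout", "reached"),
    rest_c = rest_c, direction = direction,
    rest_met_c = stats::rnorm(n, 0, 0.7),
    recovery_met_c = stats::rnorm(n, 0, 0.4),
    time_in_study_c = stats::runif(n, -2, 2))
}
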