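#' Default model formulas
#'
#' The reactivity model regresses the RMSSD difference score on group-mean
#' centered resting lnRMSSD, reactivity MET and their interaction, plus the
#' segment, time and person covariates, with a person random intercept.
#' The recovery model is deliberately lean — resting lnRMSSD, the
#' reactivity-direction dummy, their interaction, resting and recovery MET
#' and time in study — since richer covariate sets make the Poisson mixed
#' model fragile at these sample sizes. Nicotine is coded upstream but not
#' included by default for the same reason.
#'
#' @name default_formulas
NULL

#' @rdname default_formulas
#' @export
reactivity_formula <- function() {
  delta_rmssd ~ rest_c * react_met_c + rest_met_c + rest_supine_c +
    react_supine_c + time_in_study_c + caffeine + alcohol +
    anticipated_stress + ambient_noise + mvpa_hours_c + bmi_c +
    chronic_stress_z + (1 | person_id)
}

#' @rdname default_formulas
#' @export
recovery_formula <- function() {
  recovery_minutes ~ rest_c * direction + rest_met_c + recovery_met_c +
    time_in_study_c + (1 | person_id)
}

new_hrv_fit <- function(model, coef, varcomp, n_obs, n_persons, converged,
                        family) {
  structure(list(model = model, coef = coef, varcomp = varcomp,
                 n_obs = n_obs, n_persons = n_persons,
                 converged = converged, family = family),
            class = "hrv_fit")
}

check_rank <- function(formula, data) {
  fixed <- lme4::nobars(formula)
  X <- stats::model.matrix(fixed, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased terms: ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit the linear mixed model of RMSSD reactivity
#'
#' Random-intercept linear mixed model fit by REML; fixed-effect p-values
#' use Satterthwaite degrees of freedom and 95% intervals are Wald
#' (estimate +/- 1.96 SE). A near-zero random-intercept variance is
#' reported as estimated, not hidden.
#'
#' @param data Model-ready reactivity table (see
#'   [assemble_analysis_tables()] or [simulate_reactivity_table()]).
#' @param formula Mixed-model formula; default [reactivity_formula()],
#'   reduced to the terms present in `data`.
#' @return An object of class `"hrv_fit"`.
#' @export
fit_reactivity <- function(data, formula = NULL) {
  if (is.null(formula)) formula <- reactivity_formula()
  vars <- all.vars(lme4::nobars(formula))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0)
    stop("missing model columns: ", paste(missing_vars, collapse = ", "))
  if (length(unique(data$person_id)) < 2)
    stop("need at least 2 persons")
  check_rank(formula, data)
  fit <- lmerTest::lmer(formula, data = data, REML = TRUE)
  sm <- summary(fit)$coefficients
  coef_tbl <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    se = unname(sm[, "Std. Error"]),
    df = unname(sm[, "df"]),
    p = unname(sm[, "Pr(>|t|)"]),
    lower = unname(sm[, "Estimate"] - 1.96 * sm[, "Std. Error"]),
    upper = unname(sm[, "Estimate"] + 1.96 * sm[, "Std. Error"]))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble::tibble(component = c("person_intercept", "residual"),
                            variance = c(vc$vcov[vc$grp == "person_id"],
                                         vc$vcov[vc$grp == "Residual"]))
  msgs <- fit@optinfo$conv$lme4$messages
  new_hrv_fit(fit, coef_tbl, varcomp,
              n_obs = stats::nobs(fit),
              n_persons = lme4::ngrps(fit)[["person_id"]],
              converged = is.null(msgs), family = "gaussian")
}

#' Fit the Poisson mixed model of recovery minutes
#'
#' Generalized linear mixed model with Poisson family and log link on the
#' uncensored (`status == "reached"`) recoveries, fit by Laplace
#' approximation. Estimates are reported as incidence rate ratios
#' (exponentiated coefficients) with exponentiated Wald intervals; an IRR
#' above 1 is the multiplicative increase in expected recovery minutes per
#' unit predictor.
#'
#' @param data Model-ready recovery table. Rows with `status != "reached"`
#'   (pile-up and timeout censoring) are dropped before fitting.
#' @param formula Mixed-model formula; default [recovery_formula()].
#' @return An object of class `"hrv_fit"` whose `coef` carries `irr`,
#'   `irr_lower`, `irr_upper` alongside the log-scale columns.
#' @export
fit_recovery <- function(data, formula = NULL) {
  if (is.null(formula)) formula <- recovery_formula()
  if ("status" %in% names(data)) data <- data[data$status == "reached", ]
  if (nrow(data) == 0) stop("no uncensored recoveries to fit")
  y <- data$recovery_minutes
  if (any(is.na(y)) || any(y < 0) || any(y != floor(y)))
    stop("recovery minutes must be non-negative integers")
  if (all(y == 0)) stop("all-zero outcome")
  if (length(unique(data$person_id)) < 2) stop("need at least 2 persons")
  check_rank(formula, data)
  fit <- lme4::glmer(formula, data = data, family = stats::poisson())
  sm <- summary(fit)$coefficients
  coef_tbl <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    se = unname(sm[, "Std. Error"]),
    p = unname(sm[, "Pr(>|z|)"]),
    lower = unname(sm[, "Estimate"] - 1.96 * sm[, "Std. Error"]),
    upper = unname(sm[, "Estimate"] + 1.96 * sm[, "Std. Error"]))
  coef_tbl$irr <- exp(coef_tbl$estimate)
  coef_tbl$irr_lower <- exp(coef_tbl$lower)
  coef_tbl$irr_upper <- exp(coef_tbl$upper)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble::tibble(component = "person_intercept",
                            variance = vc$vcov[vc$grp == "person_id"])
  msgs <- fit@optinfo$conv$lme4$messages
  new_hrv_fit(fit, coef_tbl, varcomp,
              n_obs = stats::nobs(fit),
              n_persons = lme4::ngrps(fit)[["person_id"]],
              converged = is.null(msgs), family = "poisson")
}

#' Summarize a fitted model as report tables
#'
#' @param fit An `"hrv_fit"` object.
#' @return List with `fixed` (IRR scale for Poisson fits), `random`
#'   (variance components) and `n` (observations, persons, convergence).
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "hrv_fit"))
  fixed <- if (fit$family == "poisson")
    fit$coef[, c("term", "irr", "se", "p", "irr_lower", "irr_upper")]
  else fit$coef[, c("term", "estimate", "se", "p", "lower", "upper")]
  list(fixed = fixed, random = fit$varcomp,
       n = tibble::tibble(n_observations = fit$n_obs,
                          n_persons = fit$n_persons,
                          converged = fit$converged))
}

#' @export
print.hrv_fit <- function(x, ...) {
  cat(sprintf("<hrv_fit: %s mixed model, %d obs / %d persons%s>\n",
              x$family, x$n_obs, x$n_persons,
              if (x$converged) "" else ", convergence warnings"))
  print(as.data.frame(x$coef), digits = 3)
  cat("Random effects:\n")
  print(as.data.frame(x$varcomp), digits = 3)
  invisible(x)
}
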