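#' Classify a best-fitting model into a diversity-trajectory scenario
#'
#' Maps the winner of a model battery onto one of four trajectory
#' scenarios:
#' \itemize{
#'   \item `Sc1_gradual`: constant net diversification (constant-rate winner
#'     or a flat fitted trajectory);
#'   \item `Sc2_exponential`: net diversification increasing towards the
#'     present;
#'   \item `Sc3_saturated`: net diversification decreasing towards the
#'     present but still non-negative today;
#'   \item `Sc4_waxing_waning`: decreasing and negative at present
#'     (extinction exceeds speciation, diversity is being lost).
#' }
#' For non-constant winners the trend is the sign of the least-squares
#' slope of r(t) on a 100-point grid over `[0, crown_age]` (ages are
#' past-positive, so a positive slope means rates were higher in the past,
#' i.e. decreasing towards the present); absolute slopes below
#' `eps * mean(|r|)` count as flat.
#'
#' @param best a converged [fit_bd()] winner (non-converged fits are still
#'   classified but tagged `reliable = FALSE`).
#' @param crown_age trajectory span; defaults to the fit's crown age.
#' @param eps relative flatness threshold (default 1e-4).
#' @return an object of class `scenario_call`: list with `scenario`,
#'   `speciation_trend`, `r_present`, `reliable`, `basis`.
#' @export
classify_scenario <- function(best, crown_age = best$crown_age, eps = 1e-4) {
  stopifnot(inherits(best, "bd_fit"))
  basis <- if (best$family %in% c("temperature", "uplift"))
    "environmental_comparison" else "time_only_comparison"
  model <- fitted_model(best)
  r0 <- net_rate(model, 0)
  if (best$model_name == "constant") {
    return(structure(list(scenario = "Sc1_gradual",
                          speciation_trend = "constant",
                          r_present = r0, reliable = best$converged,
                          basis = basis), class = "scenario_call"))
  }
  tt <- seq(0, crown_age, length.out = 100L)
  r <- net_rate(model, tt)
  slope <- stats::cov(tt, r) / stats::var(tt)
  flat <- !is.finite(slope) || abs(slope) <= eps * max(mean(abs(r)), 1e-12)
  scenario <- if (flat) "Sc1_gradual"
    else if (slope > 0 && r0 >= 0) "Sc3_saturated"
    else if (slope > 0) "Sc4_waxing_waning"
    else "Sc2_exponential"
  structure(list(scenario = scenario,
                 speciation_trend = classify_speciation_trend(best, eps = eps),
                 r_present = r0, reliable = best$converged, basis = basis),
            class = "scenario_call")
}

#' @export
print.scenario_call <- function(x, ...) {
  cat(sprintf("Scenario %s (speciation %s, r(0) = %.4g%s)\n",
              x$scenario, x$speciation_trend, x$r_present,
              if (x$reliable) "" else ", unreliable"))
  invisible(x)
}

#' Direction of the fitted speciation-rate trend
#'
#' From the fitted speciation dependence: for a time-exponential speciation
#' rate, alpha > eps means decreasing towards the present (rates were
#' higher in the past), alpha < -eps increasing; a constant fitted
#' speciation rate (extinction possibly time-variable) is `"constant"`.
#' Environmental winners are judged from the realized lambda(t) trajectory
#' over the clade's own time span.
#'
#' @param best a [fit_bd()] result.
#' @param eps flatness threshold on the dependence (default 1e-4).
#' @return `"constant"`, `"increasing"`, or `"decreasing"` (towards the
#'   present).
#' @export
classify_speciation_trend <- function(best, eps = 1e-4) {
  stopifnot(inherits(best, "bd_fit"))
  tpl <- best$template
  if (tpl$lambda_form == "constant") return("constant")
  if (tpl$lambda_form == "exp_time") {
    a <- best$mle_params[["alpha"]]
    if (a > eps) return("decreasing")
    if (a < -eps) return("increasing")
    return("constant")
  }
  ## environmental form: slope of realized lambda(t) over the clade span
  model <- fitted_model(best)
  tt <- seq(0, best$crown_age, length.out = 100L)
  lam <- rate_at(model$lambda, tt)
  slope <- stats::cov(tt, lam) / stats::var(tt)
  if (abs(slope) < eps * mean(abs(lam))) "constant"
  else if (slope > 0) "decreasing" else "increasing"
}

#' Speciation-trend diagnosis from a pulled-rate fit
#'
#' A constant pulled-rate winner indicates that speciation and extinction
#' were constant or varied only slowly (`"constant"`).  For a time-variable
#' winner, a negative present-day pulled extinction rate mu_p(0) < 0 is
#' evidence that speciation is currently decreasing; a non-negative mu_p(0)
#' is compatible with both increasing and decreasing speciation, so the
#' trend is `"unknown"`.
#'
#' @param pulled a [fit_pdr()] or [select_pdr()] result.
#' @return an object of class `pulled_trend`: list with `trend` and
#'   `mu_p_present`.
#' @export
classify_pulled_trend <- function(pulled) {
  stopifnot(inherits(pulled, "pdr_fit"))
  mu_p0 <- pulled$mu_p_knots[1L]
  trend <- if (pulled$n_intervals == 1L) "constant"
           else if (mu_p0 < 0) "decreasing_speciation" else "unknown"
  structure(list(trend = trend, mu_p_present = mu_p0),
            class = "pulled_trend")
}

#' @export
print.pulled_trend <- function(x, ...) {
  cat(sprintf("Pulled speciation trend: %s (mu_p(0) = %.4g)\n",
              x$trend, x$mu_p_present))
  invisible(x)
}
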