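## Pulled diversification rates on an age grid.
##
## A birth-death-sampling congruence class is parameterized by the pulled
## diversification rate r_p(t) = lambda - mu + lambda'/lambda and the
## product rho * lambda(0).  Every member of a class yields the same
## likelihood for any extant timetree, which here is computed directly in
## the invariant parameterization:
##   R(t)    = exp(int_0^t r_p),
##   rhoJ(t) = 1 + rho*lambda0 * int_0^t R(s) ds,
##   logL    = sum_{events t_i < tau} [log(rho*lambda0*R(t_i)) - 2 log rhoJ(t_i)]
##             - m * log rhoJ(tau),
## with tau the truncation age and m the number of lineages at tau
## (tau = crown age, m = 2 for an untruncated crown tree).  This code path
## is independent of the canonical likelihood in R/likelihood.R, which is
## used as a cross-check.

#' Age grid for gridded pulled-rate estimation
#'
#' Knots are placed closer together near the present, where the information
#' content of the reconstructed tree is higher: for 3 intervals the knots
#' sit at fractions (0, 0.15, 0.40, 1) of the truncation age.
#'
#' @param truncation_age oldest age retained (> 0, see [truncation_age()]).
#' @param n_intervals 1 or 3.
#' @return ascending knot ages in Myr.
#' @export
make_age_grid <- function(truncation_age, n_intervals = 3L) {
  if (truncation_age <= 0) stop("truncation_age must be > 0")
  fr <- switch(as.character(n_intervals),
               "1" = c(0, 1), "3" = c(0, 0.15, 0.40, 1),
               stop("n_intervals must be 1 or 3"))
  fr * truncation_age
}

#' Construct a pulled diversification model
#'
#' @param knot_ages ascending ages (Myr) starting at 0.
#' @param rp_knots pulled diversification rate at each knot (Myr^-1);
#'   piecewise-linear between knots, constant beyond the oldest knot.
#' @param rho_lambda0 the identifiable product rho * lambda(0) (> 0).
#' @return an object of class `pdr_model`.
#' @export
pdr_model <- function(knot_ages, rp_knots, rho_lambda0) {
  if (length(knot_ages) != length(rp_knots))
    stop("knot_ages and rp_knots differ in length")
  if (is.unsorted(knot_ages, strictly = TRUE) || knot_ages[1L] != 0)
    stop("knot_ages must be strictly increasing from 0")
  if (rho_lambda0 <= 0) stop("rho_lambda0 must be > 0")
  structure(list(knot_ages = knot_ages, rp_knots = rp_knots,
                 rho_lambda0 = rho_lambda0),
            class = "pdr_model")
}

## r_p(t): piecewise-linear, clamped beyond the oldest knot
pdr_rate <- function(model, t) {
  stats::approx(model$knot_ages, model$rp_knots, xout = pmin(t, max(model$knot_ages)),
                rule = 2)$y
}

## exact integral of the piecewise-linear r_p from 0 to each t
pdr_rate_integral <- function(model, t) {
  x <- model$knot_ages; y <- model$rp_knots
  nk <- length(x)
  cum <- c(0, cumsum(diff(x) * (y[-nk] + y[-1L]) / 2))
  i <- pmin(pmax(findInterval(t, x), 1L), nk - 1L)
  dt <- pmin(t, x[nk]) - x[i]
  val <- cum[i] + y[i] * dt + (y[i + 1L] - y[i]) / diff(x)[i] * dt^2 / 2
  ## constant extrapolation beyond the oldest knot
  over <- t > x[nk]
  if (any(over)) val[over] <- val[over] + (t[over] - x[nk]) * y[nk]
  val
}

#' Log-likelihood of branching times under a pulled diversification model
#'
#' Likelihood of the lineage-through-time data under the homogeneous
#' birth-death-sampling congruence class parameterized by
#' `(r_p(t), rho*lambda0)`.  The value depends on a canonical model
#' `(lambda, mu, rho)` only through these pulled quantities.  When
#' `truncation` is supplied, only branching events younger than the
#' truncation age enter, and the likelihood is conditioned on the `m`
#' lineages present at that age.
#'
#' @param bt branching times (or a tree).
#' @param model a [pdr_model()].
#' @param truncation optional list as from [truncation_age()]; `NULL` uses
#'   the full crown tree (tau = crown age, m = 2).
#' @param ngrid integration grid intervals.
#' @return the log-likelihood.
#' @export
pdr_loglik <- function(bt, model, truncation = NULL, ngrid = 2000L) {
  bt <- branching_times(bt)
  if (is.null(truncation)) {
    tau <- bt$ages[1L]; ev <- bt$ages[-1L]; m <- 2L
  } else {
    tau <- truncation$age
    if (tau <= 0) stop("clade not analyzable at this truncation")
    ev <- bt$ages[bt$ages < tau]
    m <- lineage_count_at(bt, tau) + 1L  # event at tau has just occurred
  }
  ngrid <- as.integer(ngrid); if (ngrid %% 2L == 1L) ngrid <- ngrid + 1L
  s <- seq(0, tau, length.out = ngrid + 1L)
  h <- tau / ngrid
  R <- exp(pdr_rate_integral(model, s))
  if (any(!is.finite(R))) stop("non-finite exp(int r_p); r_p too extreme")
  IR <- cumsimpson(R, h)
  rhoJ <- 1 + model$rho_lambda0 * IR
  if (length(ev) > 0L) {
    i <- pmin(pmax(findInterval(ev, s), 1L), ngrid)
    u <- (ev - s[i]) / h
    R_ev <- exp(pdr_rate_integral(model, ev))
    IR_ev <- hermite_at(IR, R, i, u, h)
    rhoJ_ev <- 1 + model$rho_lambda0 * IR_ev
    ev_sum <- sum(log(model$rho_lambda0 * R_ev) - 2 * log(rhoJ_ev))
  } else ev_sum <- 0
  ev_sum - m * log(rhoJ[length(rhoJ)])
}

#' Fit a pulled diversification model by maximum likelihood
#'
#' Fits either a constant pulled-rate model (`n_intervals = 1`: one free
#' r_p value plus rho*lambda0, k = 2) or a 3-interval grid model (four
#' knot values plus rho*lambda0, k = 5) to the branching times truncated
#' to periods with more than `min_lineages` lineages.  Optimization uses 20
#' independent Latin-hypercube restarts; ranking uses plain AIC.
#'
#' @param bt branching times (or a tree).
#' @param rho sampling fraction in (0, 1], used to derive
#'   `lambda0 = rho*lambda0 / rho` and the pulled extinction rates
#'   `mu_p = lambda0 - r_p`.
#' @param n_intervals 1 (constant) or 3 (grid).
#' @param settings a [fit_settings()] list; `n_restarts` defaults to 20
#'   for pulled fits.
#' @param min_lineages truncation threshold (default 10).
#' @return an object of class `pdr_fit` with the fitted [pdr_model()],
#'   `loglik`, `k`, `AIC`, `lambda0_derived`, `mu_p_knots`, `trend`,
#'   `converged`, `truncation`.
#' @export
fit_pdr <- function(bt, rho = 1, n_intervals = 3L,
                    settings = fit_settings(n_restarts = 20L),
                    min_lineages = 10L) {
  bt <- branching_times(bt)
  trunc <- truncation_age(bt, min_lineages)
  if (!trunc$analyzable) {
    out <- structure(list(model = NULL, loglik = -Inf, k = NA_integer_,
                          AIC = Inf, n_intervals = n_intervals,
                          lambda0_derived = NA_real_, mu_p_knots = NA_real_,
                          rho = rho, converged = FALSE, flagged = TRUE,
                          truncation = trunc), class = "pdr_fit")
    return(out)
  }
  knots <- make_age_grid(trunc$age, n_intervals)
  n_free_rp <- if (n_intervals == 1L) 1L else length(knots)
  k <- n_free_rp + 1L

  rp_bound <- 5
  lower <- c(rep(-rp_bound, n_free_rp), log(1e-6))
  upper <- c(rep(rp_bound, n_free_rp), log(10))

  make_model <- function(par) {
    rp <- if (n_intervals == 1L) rep(par[1L], length(knots))
          else par[seq_len(n_free_rp)]
    pdr_model(knots, rp, exp(par[length(par)]))
  }
  negll <- function(par) {
    v <- tryCatch(pdr_loglik(bt, make_model(par), truncation = trunc,
                             ngrid = settings$ngrid),
                  error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }

  set.seed(settings$seed)
  u <- lhs_unit(settings$n_restarts, k)
  best <- NULL
  for (rs in seq_len(settings$n_restarts)) {
    start <- c((u[rs, seq_len(n_free_rp)] - 0.5) * 1.0,
               log(1e-2) + u[rs, k] * (log(2) - log(1e-2)))
    opt <- tryCatch(stats::nlminb(start, negll, lower = lower, upper = upper,
                                  control = list(iter.max = 500L)),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) {
      best <- opt; best$restart <- rs
    }
  }
  if (is.null(best)) {
    return(structure(list(model = NULL, loglik = -Inf, k = k, AIC = Inf,
                          n_intervals = n_intervals, lambda0_derived = NA_real_,
                          mu_p_knots = NA_real_, rho = rho, converged = FALSE,
                          flagged = TRUE, truncation = trunc),
                     class = "pdr_fit"))
  }
  model <- make_model(best$par)
  ll <- -best$objective
  lambda0 <- model$rho_lambda0 / rho
  out <- structure(list(model = model, loglik = ll, k = k,
                        AIC = -2 * ll + 2 * k, n_intervals = n_intervals,
                        lambda0_derived = lambda0,
                        mu_p_knots = lambda0 - model$rp_knots,
                        rho = rho, converged = best$convergence == 0,
                        flagged = FALSE, truncation = trunc,
                        best_restart_seed = best$restart),
                   class = "pdr_fit")
  out$trend <- classify_pulled_trend(out)
  out
}

#' Select between constant and 3-interval pulled models by AIC
#'
#' Minimum AIC wins; exact ties, or a missing/flagged grid fit, fall back
#' to the constant (fewer-knots) model.
#'
#' @param fit1 the 1-interval (constant) `pdr_fit`.
#' @param fit3 the 3-interval `pdr_fit` (may be flagged).
#' @return the selected `pdr_fit`, with `selected_over` recording the
#'   alternative's AIC.
#' @export
select_pdr <- function(fit1, fit3) {
  stopifnot(inherits(fit1, "pdr_fit"))
  if (is.null(fit3) || !inherits(fit3, "pdr_fit") || fit3$flagged ||
      !is.finite(fit3$AIC)) {
    fit1$selected_over <- NA_real_
    fit1$fallback <- TRUE
    return(fit1)
  }
  win <- if (fit3$AIC < fit1$AIC) fit3 else fit1
  win$selected_over <- if (fit3$AIC < fit1$AIC) fit1$AIC else fit3$AIC
  win$fallback <- FALSE
  win
}

#' Fit and select pulled models for one clade
#'
#' Convenience wrapper: fits the constant and 3-interval pulled models and
#' returns the AIC winner.
#'
#' @inheritParams fit_pdr
#' @export
fit_pdr_battery <- function(bt, rho = 1, settings = fit_settings(n_restarts = 20L),
                            min_lineages = 10L) {
  f1 <- fit_pdr(bt, rho, 1L, settings, min_lineages)
  f3 <- fit_pdr(bt, rho, 3L, settings, min_lineages)
  select_pdr(f1, f3)
}

#' @export
print.pdr_fit <- function(x, ...) {
  if (is.null(x$model)) {
    cat("Pulled-rate fit: not analyzable (tree never exceeds the lineage",
        "threshold)\n")
    return(invisible(x))
  }
  cat(sprintf("Pulled-rate fit: %d interval(s), logLik = %.4f, AIC = %.4f\n",
              x$n_intervals, x$loglik, x$AIC))
  cat("  knots (Myr):", paste(sprintf("%.3g", x$model$knot_ages), collapse = ", "), "\n")
  cat("  r_p:        ", paste(sprintf("%.4g", x$model$rp_knots), collapse = ", "), "\n")
  cat(sprintf("  rho*lambda0 = %.4g, lambda0 = %.4g, mu_p(0) = %.4g\n",
              x$model$rho_lambda0, x$lambda0_derived, x$mu_p_knots[1L]))
  if (!is.null(x$trend)) print(x$trend)
  invisible(x)
}
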