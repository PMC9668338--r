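#' Small-sample Akaike information criterion
#'
#' AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1), with n the number of tips.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (tips in the clade).
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1 (small-tree guard)")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from a vector of AICc values
#'
#' w_i proportional to exp(-dAICc_i / 2), normalized to sum to 1; models
#' with non-finite AICc get weight 0.
#'
#' @param aicc_values numeric vector (may contain `Inf`/`NA` for failed fits).
#' @export
akaike_weights <- function(aicc_values) {
  v <- as.numeric(aicc_values)
  v[is.na(v)] <- Inf
  if (!any(is.finite(v))) stop("no finite AICc values")
  d <- v - min(v)
  w <- exp(-d / 2)
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Fitting settings for birth-death and pulled-rate maximum likelihood
#'
#' @param n_restarts dispersed (Latin hypercube) starting points per model.
#' @param seed master RNG seed; fits are bit-reproducible given the seed.
#' @param ngrid integration grid intervals (see [bd_loglik()]).
#' @param lambda_bounds,mu_bounds box bounds for the baseline rates
#'   (events/lineage/Myr).
#' @param alpha_bound half-width of the box for time dependencies (Myr^-1);
#'   environmental dependencies are bounded by `8 / range(curve values)` so
#'   the exponent spans a comparable range over the curve.
#' @export
fit_settings <- function(n_restarts = 10L, seed = 1L, ngrid = 2000L,
                         lambda_bounds = c(1e-6, 10),
                         mu_bounds = c(1e-6, 10),
                         alpha_bound = 0.5) {
  list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
       ngrid = as.integer(ngrid), lambda_bounds = lambda_bounds,
       mu_bounds = mu_bounds, alpha_bound = alpha_bound)
}

## dependence bound for a given template variable
dep_bound <- function(settings, env) {
  if (is.null(env)) settings$alpha_bound
  else 8 / diff(range(env$curve$values))
}

## a model template: forms for lambda/mu plus the free-parameter layout.
## family is one of constant/time/temperature/uplift (driver classes).
bd_template <- function(name, family, lambda_form, mu_form, env = NULL) {
  free <- c("lambda0", "mu0",
            if (lambda_form != "constant") "alpha",
            if (mu_form != "constant") "beta")
  list(name = name, family = family, lambda_form = lambda_form,
       mu_form = mu_form, env = env, free = free, k = length(free))
}

#' The 10-model battery of diversification templates
#'
#' Constant rates; speciation and/or extinction exponential in time; and
#' speciation and/or extinction exponential in each of two environmental
#' curves (temperature and Andean paleo-elevation).
#'
#' @param curves named list with `smooth_env` elements `temperature` and
#'   `uplift`; either may be omitted to drop that family.
#' @return list of model templates for [fit_bd()] / [fit_battery()].
#' @export
battery_templates <- function(curves = list()) {
  tpl <- list(bd_template("constant", "constant", "constant", "constant"))
  tpl <- c(tpl, list(
    bd_template("time_lambda", "time", "exp_time", "constant"),
    bd_template("time_mu", "time", "constant", "exp_time"),
    bd_template("time_both", "time", "exp_time", "exp_time")))
  for (fam in c("temperature", "uplift")) {
    if (is.null(curves[[fam]])) next
    env <- curves[[fam]]
    tpl <- c(tpl, list(
      bd_template(paste0(fam, "_lambda"), fam, "exp_env", "constant", env),
      bd_template(paste0(fam, "_mu"), fam, "constant", "exp_env", env),
      bd_template(paste0(fam, "_both"), fam, "exp_env", "exp_env", env)))
  }
  tpl
}

## Latin hypercube in [0,1]^d, deterministic under the current RNG state
lhs_unit <- function(n, d) {
  sapply(seq_len(d), function(j) (sample.int(n) - stats::runif(n)) / n)
}

## map a template + parameter vector to grid/event rate values; X_s, X_ev
## are the precomputed covariates (age or env value) for lambda and mu
template_rates <- function(tpl, par, lamX_s, lamX_ev, muX_s, npts, nev) {
  l0 <- par[["lambda0"]]; m0 <- par[["mu0"]]
  lam_s <- if (tpl$lambda_form == "constant") rep.int(l0, npts)
           else l0 * exp(par[["alpha"]] * lamX_s)
  lam_ev <- if (nev == 0L) numeric(0)
            else if (tpl$lambda_form == "constant") rep.int(l0, nev)
            else l0 * exp(par[["alpha"]] * lamX_ev)
  mu_s <- if (tpl$mu_form == "constant") rep.int(m0, npts)
          else m0 * exp(par[["beta"]] * muX_s)
  list(lam_s = lam_s, lam_ev = lam_ev, mu_s = mu_s)
}

#' Maximum-likelihood fit of one birth-death model template
#'
#' Maximizes [bd_loglik()] over the template's free parameters with `nlminb`
#' box-constrained optimization from `n_restarts` Latin-hypercube starting
#' points.  Baseline rates are bounded in `lambda_bounds`/`mu_bounds`; time
#' dependencies in `[-alpha_bound, alpha_bound]`.  A fit that ends on a
#' bound or fails the optimizer's convergence test is returned with
#' `converged = FALSE` (never an exception).
#'
#' @param bt branching times (or a tree).
#' @param template an element of [battery_templates()], or a template name
#'   among `"constant"`, `"time_lambda"`, `"time_mu"`, `"time_both"`.
#' @param rho sampling fraction.
#' @param settings a [fit_settings()] list.
#' @param conditioning passed to the likelihood.
#' @return an object of class `bd_fit` with elements `model_name`,
#'   `mle_params`, `max_loglik`, `k`, `AICc`, `converged`,
#'   `n_restarts_used`, `best_restart_seed`, `grad_norm`, `family`.
#' @export
fit_bd <- function(bt, template = "constant", rho = 1,
                   settings = fit_settings(),
                   conditioning = "crown_survival") {
  if (is.character(template)) {
    tpl <- battery_templates()
    idx <- match(template, vapply(tpl, `[[`, "", "name"))
    if (is.na(idx)) stop("unknown template name: ", template)
    template <- tpl[[idx]]
  }
  tpl <- template
  bt <- branching_times(bt)
  if (bt$n_tips < 4L)
    warning("fewer than 3 branching events; estimates will be unstable")
  ctx <- ll_context(bt, rho, settings$ngrid)
  npts <- length(ctx$s); nev <- length(ctx$ev)

  ## covariates for the exponential dependencies, precomputed once
  covar <- function(form) {
    if (form == "exp_env")
      list(s = env_value(tpl$env, ctx$s), ev = env_value(tpl$env, ctx$ev))
    else list(s = ctx$s, ev = ctx$ev)
  }
  lc <- covar(tpl$lambda_form); mc <- covar(tpl$mu_form)

  lower <- upper <- numeric(tpl$k)
  names(lower) <- names(upper) <- tpl$free
  lower["lambda0"] <- settings$lambda_bounds[1]; upper["lambda0"] <- settings$lambda_bounds[2]
  lower["mu0"] <- settings$mu_bounds[1]; upper["mu0"] <- settings$mu_bounds[2]
  ab_l <- dep_bound(settings, if (tpl$lambda_form == "exp_env") tpl$env)
  ab_m <- dep_bound(settings, if (tpl$mu_form == "exp_env") tpl$env)
  if ("alpha" %in% tpl$free) { lower["alpha"] <- -ab_l; upper["alpha"] <- ab_l }
  if ("beta" %in% tpl$free) { lower["beta"] <- -ab_m; upper["beta"] <- ab_m }

  negll <- function(par) {
    names(par) <- tpl$free
    rates <- template_rates(tpl, par, lc$s, lc$ev, mc$s, npts, nev)
    v <- tryCatch(
      bd_core_loglik(ctx, rates$lam_s, rates$mu_s, rates$lam_ev, conditioning),
      error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }

  set.seed(settings$seed)
  u <- lhs_unit(settings$n_restarts, tpl$k)
  starts <- matrix(NA_real_, settings$n_restarts, tpl$k,
                   dimnames = list(NULL, tpl$free))
  for (j in seq_len(tpl$k)) {
    p <- tpl$free[j]
    if (p %in% c("lambda0", "mu0")) {
      ## log-uniform starts over a plausible rate range
      starts[, j] <- exp(log(1e-3) + u[, j] * (log(2) - log(1e-3)))
    } else {
      starts[, j] <- (u[, j] - 0.5) * (upper[j] - lower[j]) * 0.5
    }
  }

  best <- NULL
  for (rs in seq_len(settings$n_restarts)) {
    opt <- tryCatch(
      stats::nlminb(starts[rs, ], negll, lower = lower, upper = upper,
                    control = list(iter.max = 500L, eval.max = 1000L)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) {
      best <- opt; best$restart <- rs
    }
  }

  if (is.null(best)) {
    return(structure(list(
      model_name = tpl$name, family = tpl$family, template = tpl,
      mle_params = stats::setNames(rep(NA_real_, tpl$k), tpl$free),
      max_loglik = -Inf, k = tpl$k, n = bt$n_tips, AICc = Inf,
      converged = FALSE, n_restarts_used = settings$n_restarts,
      best_restart_seed = NA_integer_, grad_norm = NA_real_,
      rho = rho, crown_age = ctx$crown, bt = bt), class = "bd_fit"))
  }

  par <- stats::setNames(best$par, tpl$free)
  ll <- -best$objective
  at_bound <- any(par - lower < 1e-6 * pmax(1, abs(lower)) |
                  upper - par < 1e-6 * pmax(1, abs(upper)))
  ## central-difference gradient norm as a convergence diagnostic
  gn <- sqrt(sum(vapply(seq_along(par), function(j) {
    e <- pmax(1e-5, abs(par[j]) * 1e-5)
    pp <- pm <- par; pp[j] <- par[j] + e; pm[j] <- par[j] - e
    (negll(pm) - negll(pp)) / (2 * e)
  }, 0)^2))
  ic <- if (bt$n_tips > tpl$k + 1) aicc(ll, tpl$k, bt$n_tips) else Inf

  structure(list(
    model_name = tpl$name, family = tpl$family, template = tpl,
    mle_params = par, max_loglik = ll, k = tpl$k, n = bt$n_tips,
    AICc = ic, converged = best$convergence == 0 && !at_bound && gn < 1,
    n_restarts_used = settings$n_restarts, best_restart_seed = best$restart,
    grad_norm = gn, rho = rho, crown_age = ctx$crown, bt = bt),
    class = "bd_fit")
}

#' Rebuild the fitted rate model from a `bd_fit`
#' @param fit a [fit_bd()] result.
#' @return a [bd_model()] with the fitted parameters.
#' @export
fitted_model <- function(fit) {
  stopifnot(inherits(fit, "bd_fit"))
  tpl <- fit$template; p <- fit$mle_params
  lam <- rate_spec("speciation", tpl$lambda_form, p[["lambda0"]],
                   if ("alpha" %in% names(p)) p[["alpha"]] else 0,
                   env = tpl$env)
  mu <- rate_spec("extinction", tpl$mu_form, p[["mu0"]],
                  if ("beta" %in% names(p)) p[["beta"]] else 0,
                  env = tpl$env)
  bd_model(lam, mu, name = fit$model_name, k = fit$k)
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf("Birth-death fit '%s' (%d tips, rho = %.3g)\n",
              x$model_name, x$n, x$rho))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$mle_params),
                                 x$mle_params), collapse = ", "), "\n")
  cat(sprintf("  logLik = %.4f, k = %d, AICc = %.4f, converged = %s\n",
              x$max_loglik, x$k, x$AICc, x$converged))
  invisible(x)
}

#' @export
coef.bd_fit <- function(object, ...) object$mle_params

#' @export
logLik.bd_fit <- function(object, ...) {
  structure(object$max_loglik, df = object$k, nobs = object$n,
            class = "logLik")
}
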