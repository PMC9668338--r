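#' Parametric speciation or extinction rate function
#'
#' Rates are events per lineage per Myr, as functions of age t (Myr before
#' present, t = 0 now, increasing into the past):
#' \itemize{
#'   \item `constant`: rate(t) = baseline
#'   \item `exp_time`: rate(t) = baseline * exp(dependence * t).  A positive
#'     dependence (alpha for speciation, beta for extinction) means higher
#'     rates in the past, i.e. rates decreasing towards the present.
#'   \item `exp_env`: rate(t) = baseline * exp(dependence * E(t)), with E a
#'     smoothed environmental curve; the baseline is the rate at curve value
#'     zero (e.g. 0 degrees C, 0 m paleo-elevation).
#'   \item `custom`: rate(t) = fun(t); used for congruence constructions.
#' }
#'
#' @param role `"speciation"` or `"extinction"`.
#' @param form one of `"constant"`, `"exp_time"`, `"exp_env"`, `"custom"`.
#' @param baseline baseline rate (>= 0).
#' @param dependence exponent alpha/beta (Myr^-1 for `exp_time`,
#'   curve-unit^-1 for `exp_env`).
#' @param env a [fit_smooth()] object, required for `exp_env`.
#' @param fun a vectorized function of age, required for `custom`.
#' @return an object of class `rate_spec`.
#' @export
rate_spec <- function(role = c("speciation", "extinction"),
                      form = c("constant", "exp_time", "exp_env", "custom"),
                      baseline = 0.1, dependence = 0, env = NULL, fun = NULL) {
  role <- match.arg(role); form <- match.arg(form)
  if (form != "custom" && baseline < 0) stop("baseline must be >= 0")
  if (form == "exp_env" && !inherits(env, "smooth_env"))
    stop("exp_env requires a smooth_env curve")
  if (form == "custom" && !is.function(fun))
    stop("custom form requires a function of age")
  structure(list(role = role, form = form, baseline = baseline,
                 dependence = dependence, env = env, fun = fun),
            class = "rate_spec")
}

#' Evaluate a rate specification at given ages
#'
#' @param spec a [rate_spec()].
#' @param t ages in Myr before present (>= 0).
#' @return rate values (always > 0 when the baseline is > 0).
#' @export
rate_at <- function(spec, t) {
  stopifnot(inherits(spec, "rate_spec"))
  if (any(t < 0)) stop("age must be >= 0")
  switch(spec$form,
    constant = rep_len(spec$baseline, length(t)),
    exp_time = spec$baseline * exp(spec$dependence * t),
    exp_env  = spec$baseline * exp(spec$dependence * env_value(spec$env, t)),
    custom   = spec$fun(t))
}

#' Birth-death model: a speciation and an extinction rate specification
#'
#' @param lambda_spec speciation [rate_spec()].
#' @param mu_spec extinction [rate_spec()].
#' @param name model label.
#' @param k number of free parameters; derived from the specs when `NULL`
#'   (constant contributes 1 each, each exponential dependence adds 1).
#' @return an object of class `bd_model`.
#' @export
bd_model <- function(lambda_spec, mu_spec, name = "bd", k = NULL) {
  stopifnot(inherits(lambda_spec, "rate_spec"),
            inherits(mu_spec, "rate_spec"))
  if (is.null(k)) {
    npar <- function(s) switch(s$form, constant = 1L, custom = NA_integer_, 2L)
    k <- npar(lambda_spec) + npar(mu_spec)
  }
  structure(list(lambda = lambda_spec, mu = mu_spec, name = name, k = k),
            class = "bd_model")
}

#' Net diversification rate r(t) = lambda(t) - mu(t)
#'
#' @param model a [bd_model()].
#' @param t ages in Myr before present.
#' @return net rate (may be negative).
#' @export
net_rate <- function(model, t) {
  rate_at(model$lambda, t) - rate_at(model$mu, t)
}

#' @export
print.bd_model <- function(x, ...) {
  fmt <- function(s) {
    if (s$form == "constant") sprintf("%.4g", s$baseline)
    else if (s$form == "custom") "custom(t)"
    else sprintf("%.4g*exp(%+.4g*%s)", s$baseline, s$dependence,
                 if (s$form == "exp_time") "t" else paste0("E_", s$env$curve$label, "(t)"))
  }
  cat(sprintf("Birth-death model '%s' (k = %s)\n  lambda(t) = %s\n  mu(t)     = %s\n",
              x$name, x$k, fmt(x$lambda), fmt(x$mu)))
  invisible(x)
}
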