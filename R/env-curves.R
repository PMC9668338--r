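#' Build a paleoenvironmental curve from (age, value) pairs
#'
#' @param ages ages in Myr before present (>= 0).
#' @param values curve values (degrees C, metres, ...).
#' @param label short curve name (e.g. "temperature", "uplift").
#' @param units unit string carried through, never converted.
#' @return an object of class `env_curve` with ages sorted ascending and
#'   duplicate ages collapsed by their mean value.
#' @export
env_curve <- function(ages, values, label = "env", units = "") {
  ages <- as.numeric(ages); values <- as.numeric(values)
  if (length(ages) != length(values)) stop("ages and values differ in length")
  if (anyNA(ages) || anyNA(values) || any(!is.finite(values)))
    stop("non-numeric or non-finite rows in environmental table")
  if (length(ages) < 2L) stop("need at least 2 points")
  if (any(ages < 0)) stop("ages must be >= 0")
  if (anyDuplicated(ages)) {
    agg <- tapply(values, ages, mean)
    ages <- as.numeric(names(agg))
    values <- as.numeric(agg)
  }
  ord <- order(ages)
  structure(list(ages = ages[ord], values = values[ord],
                 label = label, units = units),
            class = "env_curve")
}

#' Read a two-column environmental table (age_Myr, value)
#'
#' @param path CSV file with header; first column age in Myr, second value.
#' @inheritParams env_curve
#' @export
load_env_table <- function(path, label = "env", units = "") {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("expected two columns (age_Myr, value)")
  env_curve(d[[1L]], d[[2L]], label = label, units = units)
}

#' @export
print.env_curve <- function(x, ...) {
  cat(sprintf("Environmental curve '%s' (%s): %d points, 0-%.4g Myr\n",
              x$label, x$units, length(x$ages), max(x$ages)))
  invisible(x)
}

#' Smooth an environmental curve into an evaluable function of age
#'
#' Fits a cubic smoothing spline with the requested effective degrees of
#' freedom.  With `df` equal to the number of points the curve is
#' interpolated exactly (natural cubic spline through the samples).
#' Evaluation outside the sampled age range is clamped to the boundary
#' value: no trends are extrapolated.
#'
#' @param curve an [env_curve()].
#' @param df effective degrees of freedom, between 2 and the number of
#'   points; default `min(n_points, 50)`.
#' @return an object of class `smooth_env`.
#' @export
fit_smooth <- function(curve, df = NULL) {
  stopifnot(inherits(curve, "env_curve"))
  n <- length(curve$ages)
  if (is.null(df)) df <- min(n, 50L)
  if (df < 2 || df > n) stop("df must lie in [2, n_points]")
  if (df == n || stats::var(curve$values) == 0) {
    f <- stats::splinefun(curve$ages, curve$values, method = "natural")
  } else {
    sp <- stats::smooth.spline(curve$ages, curve$values, df = df)
    f <- function(t) stats::predict(sp, t)$y
  }
  structure(list(fun = f, df = df, min_age = min(curve$ages),
                 max_age = max(curve$ages), curve = curve),
            class = "smooth_env")
}

#' Evaluate a smoothed environmental curve at an age
#'
#' Ages beyond the sampled range are clamped to the nearest boundary, so
#' clades older than the curve see the oldest sampled value.
#'
#' @param s a `smooth_env` object.
#' @param t age(s) in Myr before present (>= 0).
#' @return numeric curve value(s).
#' @export
env_value <- function(s, t) {
  stopifnot(inherits(s, "smooth_env"))
  if (any(t < 0)) stop("age must be >= 0")
  s$fun(pmin(pmax(t, s$min_age), s$max_age))
}

#' @export
print.smooth_env <- function(x, ...) {
  cat(sprintf("Smoothed '%s' curve, df = %g, domain [%.4g, %.4g] Myr\n",
              x$curve$label, x$df, x$min_age, x$max_age))
  invisible(x)
}

#' Generate a synthetic paleoenvironmental curve
#'
#' Stand-ins for published paleotemperature / paleo-elevation series:
#' a monotone `cooling_ramp`, a two-level `step` (e.g. an Eocene-Oligocene
#' style transition), or a `noisy_trend` (ramp plus seeded Gaussian noise).
#'
#' @param kind one of `"cooling_ramp"`, `"step"`, `"noisy_trend"`.
#' @param max_age oldest age (Myr), default 65.
#' @param value_range `c(value_at_present, value_at_max_age)`, default
#'   `c(12, 28)` degrees C.
#' @param step_age age of the step for `kind = "step"` (default 34 Myr).
#' @param noise_sd standard deviation for `noisy_trend` (default 1).
#' @param n_points number of samples (default 131).
#' @param seed RNG seed (mandatory for `noisy_trend`).
#' @param label,units passed to [env_curve()].
#' @export
make_synthetic_curve <- function(kind = c("cooling_ramp", "step", "noisy_trend"),
                                 max_age = 65, value_range = c(12, 28),
                                 step_age = 34, noise_sd = 1,
                                 n_points = 131L, seed = 1L,
                                 label = kind[1L], units = "degC") {
  kind <- match.arg(kind)
  ages <- seq(0, max_age, length.out = n_points)
  ramp <- value_range[1L] + (value_range[2L] - value_range[1L]) * ages / max_age
  values <- switch(kind,
    cooling_ramp = ramp,
    step = ifelse(ages < step_age, value_range[1L], value_range[2L]),
    noisy_trend = {
      set.seed(seed)
      ramp + stats::rnorm(n_points, sd = noise_sd)
    })
  env_curve(ages, values, label = label, units = units)
}
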