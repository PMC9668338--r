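## Numerical core for the reconstructed-tree birth-death likelihood.
##
## Everything is expressed through two cumulative integrals on [0, crown]:
##   F(t) = int_0^t (lambda - mu) ds          (net-rate integral)
##   I(t) = int_0^t lambda(s) exp(F(s)) ds
## With J(t) = 1/rho + I(t), the probability that a lineage alive at age t
## leaves no sampled descendant is p0(t) = 1 - exp(F(t))/J(t), and the
## log-likelihood of the branching times t1 > t2 > ... > t_{n-1}, given the
## crown age and conditioned on both crown lineages surviving to be sampled,
## collapses to
##   logL = -2 log J(t1) + sum_{i>=2} [log lambda(t_i) + F(t_i) - 2 log J(t_i)]
##          - n log rho.
## Integrals are computed on a uniform grid by a cumulative Simpson rule
## (O(h^4)) and interpolated at branching times with cubic Hermite patches
## using the exactly known derivatives F' = r and I' = lambda e^F.

## cumulative Simpson integral of y sampled at uniform spacing h;
## length(y) must be odd (even number of intervals); O(h^4).
cumsimpson <- function(y, h) {
  n <- length(y)
  stopifnot(n >= 3L, n %% 2L == 1L)
  i0 <- seq.int(1L, n - 2L, by = 2L)
  a <- h / 12 * (5 * y[i0] + 8 * y[i0 + 1L] - y[i0 + 2L])
  b <- h / 12 * (-y[i0] + 8 * y[i0 + 1L] + 5 * y[i0 + 2L])
  inc <- numeric(n - 1L)
  inc[i0] <- a
  inc[i0 + 1L] <- b
  c(0, cumsum(inc))
}

## cubic Hermite interpolation of (v, d = v') from a uniform grid x at
## precomputed interval indices i and local coordinates u in [0,1]
hermite_at <- function(v, d, i, u, h) {
  u2 <- u * u; u3 <- u2 * u
  (2 * u3 - 3 * u2 + 1) * v[i] + (u3 - 2 * u2 + u) * h * d[i] +
    (-2 * u3 + 3 * u2) * v[i + 1L] + (u3 - u2) * h * d[i + 1L]
}

## per-fit cache: grid, spacing, event interpolation coordinates
ll_context <- function(bt, rho, ngrid = 2000L) {
  bt <- branching_times(bt)
  if (rho <= 0 || rho > 1) stop("sampling fraction rho must be in (0, 1]")
  ngrid <- as.integer(ngrid)
  if (ngrid %% 2L == 1L) ngrid <- ngrid + 1L
  crown <- bt$ages[1L]
  s <- seq(0, crown, length.out = ngrid + 1L)
  h <- crown / ngrid
  ev <- bt$ages[-1L]
  if (length(ev) > 0L) {
    i <- pmin(pmax(findInterval(ev, s), 1L), ngrid)
    u <- (ev - s[i]) / h
  } else {
    i <- integer(0); u <- numeric(0)
  }
  list(bt = bt, rho = rho, crown = crown, s = s, h = h,
       ev = ev, ev_i = i, ev_u = u, n = bt$n_tips)
}

## engine: rates already evaluated on the grid (lam_s, mu_s) and at the
## branching events (lam_ev); returns the conditioned log-likelihood
bd_core_loglik <- function(ctx, lam_s, mu_s, lam_ev,
                           conditioning = "crown_survival") {
  if (any(!is.finite(lam_s)) || any(!is.finite(mu_s)))
    stop("non-finite rate values on the integration grid")
  if (any(lam_s < 0)) return(-Inf)
  Fi <- cumsimpson(lam_s - mu_s, ctx$h)
  g <- lam_s * exp(Fi)
  if (any(!is.finite(g)))
    stop("non-finite integrand int lambda*exp(F): rates too extreme for ",
         "this crown age")
  Ii <- cumsimpson(g, ctx$h)
  Jtop <- 1 / ctx$rho + Ii[length(Ii)]
  if (!is.finite(Jtop) || Jtop <= 0)
    stop("non-finite cumulative integral at the crown")
  if (length(ctx$ev) > 0L) {
    if (any(lam_ev <= 0)) return(-Inf)
    F_ev <- hermite_at(Fi, lam_s - mu_s, ctx$ev_i, ctx$ev_u, ctx$h)
    I_ev <- hermite_at(Ii, g, ctx$ev_i, ctx$ev_u, ctx$h)
    J_ev <- 1 / ctx$rho + I_ev
    if (any(J_ev <= 0)) return(-Inf)  # interpolation overshoot at extreme rates
    ev_sum <- sum(log(lam_ev) + F_ev - 2 * log(J_ev))
  } else ev_sum <- 0
  base <- ev_sum - ctx$n * log(ctx$rho)
  if (conditioning == "crown_survival") {
    base - 2 * log(Jtop)
  } else {
    ## given the crown split only, without survival conditioning
    base + 2 * (Fi[length(Fi)] - 2 * log(Jtop))
  }
}

#' Log-likelihood of branching times under a birth-death model
#'
#' Likelihood of a reconstructed (extant, sampled) timetree under a
#' birth-death process with time- or environment-dependent rates and uniform
#' species sampling, conditioned on the crown age and, by default, on the
#' survival of both crown lineages.  The value depends on the tree only
#' through its branching times.
#'
#' @param bt a [branching_times()] object (or a tree).
#' @param model a [bd_model()].
#' @param rho sampling fraction in (0, 1].
#' @param conditioning `"crown_survival"` (default) or `"crown_only"`.
#' @param ngrid number of uniform integration intervals over
#'   `[0, crown_age]` (default 2000; cumulative rate integrals are cached on
#'   this grid and reused within a fit).
#' @return the log-likelihood (finite, or `-Inf` when a branching event
#'   falls where the speciation rate is zero).
#' @export
bd_loglik <- function(bt, model, rho = 1,
                      conditioning = c("crown_survival", "crown_only"),
                      ngrid = 2000L) {
  conditioning <- match.arg(conditioning)
  ctx <- ll_context(bt, rho, ngrid)
  lam_s <- rate_at(model$lambda, ctx$s)
  mu_s <- rate_at(model$mu, ctx$s)
  lam_ev <- if (length(ctx$ev) > 0L) rate_at(model$lambda, ctx$ev) else numeric(0)
  bd_core_loglik(ctx, lam_s, mu_s, lam_ev, conditioning)
}
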