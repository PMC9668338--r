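#' Fit the full model battery to one clade and rank models by AICc
#'
#' Fits the constant-rate model, the three time-dependent models, and (when
#' curves are supplied) the three temperature-dependent and three
#' uplift-dependent models, then ranks them by AICc with Akaike weights.
#' Per-model failures are captured (the model gets `AICc = Inf`), so the
#' battery always completes.  The best model is the strict AICc minimum;
#' ties below 1e-6 are broken towards fewer parameters.
#'
#' @param bt branching times (or a tree).
#' @param rho sampling fraction in (0, 1].
#' @param curves named list of `smooth_env` curves (`temperature`,
#'   `uplift`); with `NULL` curves only the four time/constant models run.
#' @param settings a [fit_settings()] list.
#' @param templates optional explicit template list (overrides `curves`).
#' @return an object of class `bd_battery`: a list with `table` (one row
#'   per model: name, family, k, loglik, AICc, dAICc, weight, parameters),
#'   `fits`, `best`, `second_best`.
#' @export
fit_battery <- function(bt, rho = 1, curves = list(),
                        settings = fit_settings(), templates = NULL) {
  if (is.null(templates)) templates <- battery_templates(curves)
  bt <- branching_times(bt)
  fits <- vector("list", length(templates))
  for (i in seq_along(templates)) {
    st <- settings
    st$seed <- settings$seed + i  # distinct, reproducible per-model streams
    fits[[i]] <- tryCatch(
      fit_bd(bt, templates[[i]], rho, st),
      error = function(e) {
        tpl <- templates[[i]]
        structure(list(model_name = tpl$name, family = tpl$family,
                       template = tpl,
                       mle_params = stats::setNames(rep(NA_real_, tpl$k), tpl$free),
                       max_loglik = -Inf, k = tpl$k, n = bt$n_tips,
                       AICc = Inf, converged = FALSE,
                       n_restarts_used = st$n_restarts,
                       best_restart_seed = NA_integer_, grad_norm = NA_real_,
                       rho = rho, crown_age = bt$ages[1L], bt = bt,
                       error = conditionMessage(e)),
                  class = "bd_fit")
      })
  }
  names(fits) <- vapply(fits, `[[`, "", "model_name")

  ic <- vapply(fits, `[[`, 0, "AICc")
  k <- vapply(fits, `[[`, 0L, "k")
  ## strict min AICc; sub-1e-6 ties to the smaller k
  ord <- order(ic, k)
  best_i <- ord[1L]
  if (length(ord) > 1L && ic[ord[2L]] - ic[best_i] < 1e-6 &&
      k[ord[2L]] < k[best_i]) best_i <- ord[2L]
  second_i <- setdiff(ord, best_i)[1L]

  tab <- data.frame(
    model = names(fits),
    family = vapply(fits, `[[`, "", "family"),
    k = k,
    loglik = vapply(fits, `[[`, 0, "max_loglik"),
    AICc = ic,
    dAICc = ic - min(ic[is.finite(ic)]),
    weight = akaike_weights(ic),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    row.names = NULL)
  for (p in c("lambda0", "mu0", "alpha", "beta")) {
    tab[[p]] <- vapply(fits, function(f) {
      if (p %in% names(f$mle_params)) unname(f$mle_params[[p]]) else NA_real_
    }, 0)
  }

  structure(list(table = tab, fits = fits,
                 best = fits[[best_i]], second_best = fits[[second_i]],
                 rho = rho, n = bt$n_tips, settings = settings),
            class = "bd_battery")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bd_battery <- function(x, ...) {
  cat(sprintf("Model battery: %d models on %d tips (rho = %.3g)\n",
              nrow(x$table), x$n, x$rho))
  tab <- x$table[order(x$table$AICc), c("model", "family", "k", "loglik",
                                        "AICc", "dAICc", "weight")]
  print(format(tab, digits = 4), row.names = FALSE)
  cat("Best model:", x$best$model_name, "\n")
  invisible(x)
}

#' @export
summary.bd_battery <- function(object, ...) {
  cl <- classify_scenario(object$best)
  cat(sprintf("Best model: %s (AICc weight %.3f); scenario %s, %s speciation\n",
              object$best$model_name,
              object$table$weight[object$table$model == object$best$model_name],
              cl$scenario, cl$speciation_trend))
  invisible(object)
}
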