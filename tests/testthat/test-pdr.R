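test_that("age grids are front-loaded towards the present", {
  expect_equal(make_age_grid(20, 3), c(0, 3, 8, 20))
  expect_equal(make_age_grid(20, 1), c(0, 20))
  set.seed(1)
  for (tau in runif(20, 0.01, 100))
    expect_true(all(diff(make_age_grid(tau, 3)) > 0))
  expect_error(make_age_grid(0, 3), "> 0")
  expect_error(make_age_grid(10, 2), "1 or 3")
})

test_that("pulled likelihood equals the canonical likelihood on matched models", {
  set.seed(17)
  bt <- new_branching_times(c(15, sort(runif(18, 0.3, 14.7),
                                       decreasing = TRUE)))
  ## constant canonical (0.3, 0.1, rho = 1) <-> pulled (r_p = 0.2, 0.3)
  canon <- bd_model(rate_spec("speciation", "constant", 0.3),
                    rate_spec("extinction", "constant", 0.1))
  pm <- pdr_model(c(0, 15), c(0.2, 0.2), 0.3)
  expect_equal(pdr_loglik(bt, pm), bd_loglik(bt, canon, 1),
               tolerance = 1e-6)

  ## sampling-scaling invariance: rho halved, lambda0 doubled
  canon2 <- bd_model(rate_spec("speciation", "constant", 0.6),
                     rate_spec("extinction", "constant", 0.4))
  expect_equal(pdr_loglik(bt, pm), bd_loglik(bt, canon2, 0.5),
               tolerance = 1e-6)

  ## non-constant r_p against the canonical representative
  pm2 <- pdr_model(c(0, 2, 6, 15), c(-0.1, 0.25, 0.1, 0.4), 0.35)
  rep2 <- bd_model(rate_spec("speciation", "constant", 0.35),
                   rate_spec("extinction", "custom",
                             fun = function(t) 0.35 - neodiv:::pdr_rate(pm2, t)))
  expect_equal(pdr_loglik(bt, pm2), bd_loglik(bt, rep2, 1), tolerance = 1e-6)
})

test_that("pulled likelihood is invariant across congruent canonical pairs", {
  set.seed(41)
  for (rep in 1:20) {
    n_ev <- sample(8:25, 1)
    T <- runif(1, 5, 40)
    bt <- new_branching_times(c(T, sort(runif(n_ev, 0.05, T * 0.99),
                                        decreasing = TRUE)))
    l0 <- runif(1, 0.1, 0.5); a <- runif(1, -0.06, 0.06)
    mu0 <- runif(1, 0.01, 0.2); rhoA <- runif(1, 0.3, 1)
    A <- bd_model(rate_spec("speciation", "exp_time", l0, a),
                  rate_spec("extinction", "constant", mu0))
    lamB <- rhoA * l0
    rp <- function(t) l0 * exp(a * t) - mu0 + a
    B <- bd_model(rate_spec("speciation", "constant", lamB),
                  rate_spec("extinction", "custom",
                            fun = function(t) lamB - rp(t)))
    expect_equal(bd_loglik(bt, A, rhoA), bd_loglik(bt, B, 1),
                 tolerance = 1e-6)
  }
})

test_that("pulled fits are deterministic and carry the mu_p identity", {
  lam <- rate_spec("speciation", "constant", 0.3)
  mu <- rate_spec("extinction", "constant", 0.1)
  bt <- simulate_tree(lam, mu, 18, 0.8, seed = 21, output = "bt")
  st <- fit_settings(n_restarts = 8, seed = 5, ngrid = 600)
  f1 <- fit_pdr(bt, 0.8, 3L, st)
  f2 <- fit_pdr(bt, 0.8, 3L, st)
  expect_identical(f1$model$rp_knots, f2$model$rp_knots)
  expect_identical(f1$loglik, f2$loglik)
  ## identities: lambda0 = rho_lambda0 / rho, mu_p = lambda0 - r_p, AIC/k
  expect_equal(f1$lambda0_derived, f1$model$rho_lambda0 / 0.8)
  expect_equal(f1$mu_p_knots, f1$lambda0_derived - f1$model$rp_knots)
  expect_equal(f1$AIC, -2 * f1$loglik + 2 * f1$k)
  expect_equal(f1$k, 5L)
  expect_equal(fit_pdr(bt, 0.8, 1L, st)$k, 2L)
})

test_that("constant pulled model wins on constant-rate data and recovers r", {
  lam <- rate_spec("speciation", "constant", 0.3)
  mu <- rate_spec("extinction", "constant", 0.1)
  win_const <- 0; rp_hat <- numeric(0); n_used <- 0
  for (s in 1:8) {
    bt <- simulate_tree(lam, mu, 20, 1, seed = 100 + s, output = "bt",
                        max_lineages = 5000)
    if (bt$n_tips < 40) next
    n_used <- n_used + 1
    st1 <- fit_settings(n_restarts = 12, seed = s, ngrid = 600)
    f1 <- fit_pdr(bt, 1, 1L, st1)
    f3 <- fit_pdr(bt, 1, 3L, fit_settings(n_restarts = 12, seed = s + 50,
                                          ngrid = 600))
    sel <- select_pdr(f1, f3)
    if (sel$n_intervals == 1L) win_const <- win_const + 1
    rp_hat <- c(rp_hat, f1$model$rp_knots[1])
  }
  expect_gte(n_used, 5)
  expect_gt(win_const / n_used, 0.5)
  expect_lt(abs(median(rp_hat) - 0.2) / 0.2, 0.2)
})

test_that("model selection prefers the constant model on ties and failures", {
  f1 <- structure(list(AIC = 100, n_intervals = 1L, flagged = FALSE,
                       mu_p_knots = 0.1),
                  class = "pdr_fit")
  f3 <- structure(list(AIC = 105.2, n_intervals = 3L, flagged = FALSE,
                       mu_p_knots = -0.1),
                  class = "pdr_fit")
  expect_equal(select_pdr(f1, f3)$n_intervals, 1L)
  f3$AIC <- 100
  expect_equal(select_pdr(f1, f3)$n_intervals, 1L)
  f3$AIC <- 90
  expect_equal(select_pdr(f1, f3)$n_intervals, 3L)
  f3$flagged <- TRUE
  sel <- select_pdr(f1, f3)
  expect_equal(sel$n_intervals, 1L)
  expect_true(sel$fallback)
})

test_that("small trees are flagged un-analyzable for gridded estimation", {
  bt <- new_branching_times(c(9, 6, 4, 2, 1), 6L)
  f <- fit_pdr(bt, 1, 3L, fit_settings(n_restarts = 2, seed = 1, ngrid = 300))
  expect_true(f$flagged)
  expect_false(f$converged)
  expect_identical(f$AIC, Inf)
})
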