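test_that("rate specifications evaluate their closed forms", {
  expect_equal(rate_at(rate_spec("speciation", "constant", 0.1), c(0, 5, 50)),
               rep(0.1, 3))
  expect_equal(rate_at(rate_spec("speciation", "exp_time", 0.2, 0.05), 10),
               0.2 * exp(0.5))
  ramp <- fit_smooth(env_curve(c(0, 10), c(4, 4)), df = 2)
  expect_equal(rate_at(rate_spec("speciation", "exp_env", 0.1, 0.1,
                                 env = ramp), 3),
               0.1 * exp(0.4), tolerance = 1e-9)
  expect_error(rate_at(rate_spec("speciation", "constant", 0.1), -2), ">= 0")
  expect_error(rate_spec("speciation", "exp_env", 0.1, 0.1), "smooth_env")
})

test_that("net diversification is lambda minus mu and may be negative", {
  m <- bd_model(rate_spec("speciation", "constant", 0.3),
                rate_spec("extinction", "constant", 0.1))
  expect_equal(net_rate(m, c(0, 7, 30)), rep(0.2, 3))
  eq <- bd_model(rate_spec("speciation", "constant", 0.2),
                 rate_spec("extinction", "constant", 0.2))
  expect_equal(net_rate(eq, 5), 0)
  neg <- bd_model(rate_spec("speciation", "exp_time", 0.2, 0.1),
                  rate_spec("extinction", "constant", 0.25))
  expect_equal(net_rate(neg, 0), -0.05)
  expect_equal(m$k, 2L)
  expect_equal(neg$k, 3L)
})

test_that("likelihood matches the constant-rate closed-form oracle to 1e-8", {
  bt <- new_branching_times(c(10, 6, 3))
  for (par in list(c(0.2, 0.1, 1), c(0.2, 0.1, 0.6), c(0.5, 0.45, 1),
                   c(0.3, 0.05, 0.3))) {
    m <- bd_model(rate_spec("speciation", "constant", par[1]),
                  rate_spec("extinction", "constant", par[2]))
    expect_equal(bd_loglik(bt, m, par[3]),
                 oracle_const_loglik(bt$ages, par[1], par[2], par[3]),
                 tolerance = 1e-8)
  }
  ## and on a larger random set of branching times
  set.seed(12)
  big <- new_branching_times(c(25, sort(runif(40, 0.1, 24.9),
                                        decreasing = TRUE)))
  m <- bd_model(rate_spec("speciation", "constant", 0.25),
                rate_spec("extinction", "constant", 0.12))
  expect_equal(bd_loglik(big, m, 0.7),
               oracle_const_loglik(big$ages, 0.25, 0.12, 0.7),
               tolerance = 1e-8)
})

test_that("likelihood reduces to the Yule closed form at mu = 0, rho = 1", {
  bt <- new_branching_times(c(10, 6, 3))
  m <- bd_model(rate_spec("speciation", "constant", 0.2),
                rate_spec("extinction", "constant", 0))
  expect_equal(bd_loglik(bt, m, 1), oracle_yule_loglik(bt$ages, 0.2),
               tolerance = 1e-10)
  set.seed(3)
  big <- new_branching_times(c(12, sort(runif(20, 0.1, 11.9),
                                        decreasing = TRUE)))
  expect_equal(bd_loglik(big, m, 1), oracle_yule_loglik(big$ages, 0.2),
               tolerance = 1e-10)
})

test_that("exp_time with zero dependence equals the constant model", {
  bt <- new_branching_times(c(10, 6, 3))
  m0 <- bd_model(rate_spec("speciation", "constant", 0.2),
                 rate_spec("extinction", "constant", 0.1))
  me <- bd_model(rate_spec("speciation", "exp_time", 0.2, 0),
                 rate_spec("extinction", "exp_time", 0.1, 0))
  expect_equal(bd_loglik(bt, me, 0.8), bd_loglik(bt, m0, 0.8),
               tolerance = 1e-10)
})

test_that("likelihood depends on branching times only, not topology or labels", {
  bal <- parse_newick("((A:3,B:3):7,(C:6,D:6):4);")
  pec <- parse_newick("(((X:3,Y:3):3,Z:6):4,W:10);")
  m <- bd_model(rate_spec("speciation", "exp_time", 0.3, 0.05),
                rate_spec("extinction", "constant", 0.1))
  expect_equal(bd_loglik(branching_times(bal), m, 0.9),
               bd_loglik(branching_times(pec), m, 0.9), tolerance = 1e-12)
})

test_that("congruent canonical models give equal log-likelihoods", {
  ## pairs share r_p(t) and rho*lambda0: B has constant lambda = rhoA*lamA(0),
  ## rhoB = 1, muB = lambdaB - r_p
  set.seed(30)
  for (rep in 1:5) {
    ages <- c(15, sort(runif(12 + rep, 0.2, 14.8), decreasing = TRUE))
    bt <- new_branching_times(ages)
    l0 <- runif(1, 0.15, 0.4); a <- runif(1, -0.08, 0.08)
    mu0 <- runif(1, 0.02, 0.12); rhoA <- runif(1, 0.4, 1)
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

test_that("likelihood is continuous in the parameters near an interior point", {
  bt <- new_branching_times(c(10, 7, 4, 2))
  base <- c(l0 = 0.3, m0 = 0.1, a = 0.05)
  ll <- function(p) bd_loglik(bt, bd_model(
    rate_spec("speciation", "exp_time", p["l0"], p["a"]),
    rate_spec("extinction", "constant", p["m0"])), 0.8)
  v0 <- ll(base)
  for (h in c(1e-3, 1e-4)) {
    for (j in names(base)) {
      p <- base; p[j] <- p[j] + h
      expect_lt(abs(ll(p) - v0), 50 * h)  # bounded difference quotient
    }
  }
})

test_that("degenerate rates are handled: zero speciation gives -Inf", {
  bt <- new_branching_times(c(10, 6, 3))
  m <- bd_model(rate_spec("speciation", "constant", 0),
                rate_spec("extinction", "constant", 0.1))
  expect_identical(bd_loglik(bt, m, 1), -Inf)
  expect_error(bd_loglik(bt, m, 0), "rho")
})

test_that("an extra recent branching changes the likelihood by ~log lambda", {
  m <- bd_model(rate_spec("speciation", "constant", 0.3),
                rate_spec("extinction", "constant", 0.1))
  bt1 <- new_branching_times(c(10, 6, 3))
  bt2 <- new_branching_times(c(10, 6, 3, 0.01))
  d <- bd_loglik(bt2, m, 1) - bd_loglik(bt1, m, 1)
  expect_true(is.finite(d))
  expect_lt(abs(d - log(0.3)), 0.5)
})

test_that("simulated 3-tip branching-time density matches the likelihood", {
  ## Monte-Carlo histogram against exp(loglik) under a time-varying model
  lam <- rate_spec("speciation", "exp_time", 0.25, 0.08)
  mu <- rate_spec("extinction", "constant", 0.1)
  T <- 8
  set.seed(77)
  t2 <- numeric(0)
  for (i in 1:6000) {
    b <- simulate_tree(lam, mu, T, 1, output = "bt")
    if (b$n_tips == 3L) t2 <- c(t2, b$ages[2])
  }
  expect_gt(length(t2), 60)
  breaks <- seq(0, T, length.out = 5)
  obs <- as.numeric(table(cut(t2, breaks)))
  model <- bd_model(lam, mu)
  dens <- function(x) exp(vapply(x, function(v)
    bd_loglik(new_branching_times(c(T, v)), model, 1), 0))
  expc <- vapply(seq_len(4), function(i)
    stats::integrate(dens, breaks[i], breaks[i + 1])$value, 0)
  expc <- expc / sum(expc) * length(t2)
  z <- (obs - expc) / sqrt(expc * (1 - expc / length(t2)))
  expect_true(all(abs(z) < 3.5))
})
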