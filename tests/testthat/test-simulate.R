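test_that("Yule simulations match the closed-form expected richness", {
  lam <- rate_spec("speciation", "constant", 0.1)
  mu <- rate_spec("extinction", "constant", 0)
  set.seed(11)
  tips <- replicate(400, simulate_tree(lam, mu, 10, 1, output = "bt")$n_tips)
  se <- sd(tips) / sqrt(length(tips))
  expect_lt(abs(mean(tips) - 2 * exp(1)), 3 * se)
  ## mu = 0, rho = 1: every event age within (0, crown]
  b <- simulate_tree(lam, mu, 10, 1, seed = 2, output = "bt")
  expect_true(all(b$ages > 0 & b$ages <= 10))
})

test_that("time-varying thinning matches the inhomogeneous growth expectation", {
  ## pure birth with lambda(t) = l0 e^{a t}: E[N] = 2 exp(int lambda)
  lam <- rate_spec("speciation", "exp_time", 0.05, 0.15)
  mu <- rate_spec("extinction", "constant", 0)
  set.seed(23)
  tips <- replicate(300, simulate_tree(lam, mu, 12, 1, output = "bt")$n_tips)
  expected <- 2 * exp(0.05 * (exp(0.15 * 12) - 1) / 0.15)
  se <- sd(tips) / sqrt(length(tips))
  expect_lt(abs(mean(tips) - expected), 3 * se)
})

test_that("simulated trees are valid ultrametric crown trees", {
  lam <- rate_spec("speciation", "constant", 0.4)
  mu <- rate_spec("extinction", "constant", 0.15)
  for (s in 1:5) {
    tr <- simulate_tree(lam, mu, 9, 0.7, seed = 60 + s)
    expect_s3_class(tr, "clade_tree")            # passes parse-level checks
    expect_error(parse_newick(ape::write.tree(tr)), NA)
    expect_equal(max(ape::branching.times(tr)), 9, tolerance = 1e-8)
    expect_gte(attr(tr, "n_extant"), ape::Ntip(tr))
  }
  ## impossible conditioning trips the rejection cap
  tiny <- rate_spec("speciation", "constant", 1e-4)
  doomed <- rate_spec("extinction", "constant", 5)
  expect_error(simulate_tree(tiny, doomed, 10, 1, seed = 1,
                             max_attempts = 50L),
               "rejection cap")
})

test_that("simulation is reproducible from the seed", {
  lam <- rate_spec("speciation", "exp_time", 0.2, 0.05)
  mu <- rate_spec("extinction", "constant", 0.08)
  t1 <- simulate_tree(lam, mu, 12, 0.8, seed = 77)
  t2 <- simulate_tree(lam, mu, 12, 0.8, seed = 77)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("planted abundance matrices are block-structured and seeded", {
  ab0 <- simulate_abundance(20, n_regions = 8, k_true = 4, mixing_noise = 0,
                            seed = 5)
  block <- attr(ab0, "block")
  home <- attr(ab0, "home")
  for (i in seq_len(nrow(ab0)))
    expect_equal(sum(ab0[i, block != home[i]]), 0)
  expect_identical(simulate_abundance(20, k_true = 5, seed = 9),
                   simulate_abundance(20, k_true = 5, seed = 9))
  expect_error(simulate_abundance(5, n_regions = 4, k_true = 6), "exceed")
})

test_that("synthetic studies carry consistent records, truths and abundances", {
  cfg <- sim_config(n_clades = 16L, seed = 42L,
                    size_meanlog = log(40), size_sdlog = 0.5,
                    size_range = c(7, 200), age_range = c(2, 40))
  st <- simulate_study(cfg)
  expect_equal(nrow(st$records), 16L)
  expect_equal(nrow(st$truth), 16L)
  for (i in seq_len(16)) {
    expect_equal(st$records$n_sampled[i], ape::Ntip(st$trees[[i]]))
    expect_lte(st$records$sampling_fraction[i], 1)
    expect_equal(st$records$crown_age[i], st$truth$crown_age[i],
                 tolerance = 1e-8)
  }
  ## truths stored for every clade make recovery scoring possible
  expect_true(all(c("lambda0", "mu0", "alpha", "scenario") %in%
                  names(st$truth)))
  expect_equal(colnames(st$abundance), neotropical_regions())
  expect_equal(rowSums(st$abundance), st$records$n_described,
               ignore_attr = TRUE)
  ## reproducibility: identical study from the same config
  st2 <- simulate_study(cfg)
  expect_identical(st$records, st2$records)
  expect_identical(lapply(st$trees, ape::write.tree),
                   lapply(st2$trees, ape::write.tree))
})

test_that("scenario regimes generate the intended rate signs", {
  for (sc in c("Sc1_gradual", "Sc2_exponential", "Sc3_saturated",
               "Sc4_waxing_waning")) {
    p <- neodiv:::scenario_params(sc, T = 25, n_target = 80, rho = 0.6)
    expect_gt(p$lambda0, 0)
    r0 <- p$lambda0 - p$mu0
    switch(sc,
      Sc1_gradual = expect_equal(p$alpha, 0),
      Sc2_exponential = expect_lt(p$alpha, 0),
      Sc3_saturated = { expect_gt(p$alpha, 0); expect_gte(r0, 0) },
      Sc4_waxing_waning = { expect_gt(p$alpha, 0); expect_lt(r0, 0) })
  }
})

test_that("recovery scoring tallies confusion and parameter errors", {
  st <- list(truth = data.frame(
    scenario = c("Sc1_gradual", "Sc2_exponential", "Sc3_saturated"),
    lambda0 = c(0.2, 0.3, 0.4), mu0 = c(0.1, 0.1, 0.2)))
  perfect <- score_recovery(st, st$truth$scenario)
  expect_equal(perfect$accuracy, 1)
  expect_equal(sum(diag(perfect$confusion)), 3L)
  wrong <- score_recovery(st, rep("Sc1_gradual", 3),
                          params = data.frame(lambda0 = c(0.25, 0.3, 0.4),
                                              mu0 = c(0.1, 0.1, 0.2)))
  expect_equal(wrong$accuracy, 1 / 3)
  expect_equal(wrong$param_errors$lambda0_rel[1], 0.25, tolerance = 1e-12)
})
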