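#' Simulate a reconstructed tree under a (time-varying) birth-death model
#'
#' Forward simulation from two crown lineages with time-varying rates
#' (thinning algorithm for inhomogeneous event times), followed by pruning
#' of extinct lineages and Bernoulli(rho) sampling of the surviving
#' species.  The simulation is conditioned by rejection on both crown
#' lineages leaving at least one sampled descendant, matching the
#' likelihood's crown-and-survival conditioning, so the returned tree is
#' ultrametric with the requested crown age.
#'
#' @param lambda_spec,mu_spec [rate_spec()] objects evaluable on
#'   `[0, crown_age]`.
#' @param crown_age crown age in Myr.
#' @param rho sampling fraction in (0, 1].
#' @param seed optional RNG seed (the simulation uses the current RNG
#'   state when `NULL`).
#' @param max_attempts rejection cap; exceeding it is an error suggesting
#'   a parameter change.
#' @param max_lineages guard against runaway radiations within an attempt.
#' @param output `"phylo"` (default) for a tree, or `"bt"` for the
#'   reconstructed [branching_times()] only (much faster; used by
#'   Monte-Carlo density checks).
#' @return a `clade_tree` (phylo) with attributes `n_extant` (species
#'   richness before sampling) and `attempts`, or a `branching_times`
#'   object with the same attributes.
#' @export
simulate_tree <- function(lambda_spec, mu_spec, crown_age, rho = 1,
                          seed = NULL, max_attempts = 1e5L,
                          max_lineages = 1e4L, output = c("phylo", "bt")) {
  output <- match.arg(output)
  if (!is.null(seed)) set.seed(seed)
  if (crown_age <= 0) stop("crown_age must be > 0")
  grid <- seq(0, crown_age, length.out = 257L)
  lam_max <- max(rate_at(lambda_spec, grid)) * 1.0001
  mu_max <- max(rate_at(mu_spec, grid)) * 1.0001
  if (!is.finite(lam_max + mu_max) || lam_max <= 0)
    stop("rates not finite/positive on [0, crown_age]")
  tot_max <- lam_max + mu_max

  for (attempt in seq_len(max_attempts)) {
    ## lineage bookkeeping: birth/end ages, parent, crown side, status
    n_alloc <- 256L
    parent <- integer(n_alloc); birth <- end <- numeric(n_alloc)
    side <- integer(n_alloc); extant <- logical(n_alloc)
    n_lin <- 2L
    parent[1:2] <- 0L; birth[1:2] <- crown_age; side[1:2] <- 1:2
    active <- c(1L, 2L)
    t <- crown_age
    overflow <- FALSE
    repeat {
      k <- length(active)
      t <- t - stats::rexp(1L, k * tot_max)
      if (t <= 0) break
      u <- stats::runif(1L)
      who <- active[sample.int(k, 1L)]
      lam_t <- rate_at(lambda_spec, t)
      if (u < lam_t / tot_max) {
        ## speciation: the lineage ends, two children start
        if (n_lin + 2L > n_alloc) {
          n_alloc <- n_alloc * 2L
          length(parent) <- n_alloc; length(birth) <- n_alloc
          length(end) <- n_alloc; length(side) <- n_alloc
          length(extant) <- n_alloc
          parent[is.na(parent)] <- 0L
        }
        end[who] <- t
        kids <- n_lin + 1:2
        parent[kids] <- who; birth[kids] <- t; side[kids] <- side[who]
        n_lin <- n_lin + 2L
        active <- c(active[active != who], kids)
        if (length(active) > max_lineages) { overflow <- TRUE; break }
      } else if (u < (lam_t + rate_at(mu_spec, t)) / tot_max) {
        end[who] <- t
        active <- active[active != who]
        if (length(active) == 0L) break
      }
    }
    if (overflow) next
    if (length(active) == 0L) next
    extant[active] <- TRUE
    end[active] <- 0
    n_extant <- length(active)
    sampled <- active[stats::runif(n_extant) < rho]
    if (length(sampled) < 2L) next
    if (length(unique(side[sampled])) < 2L) next

    out <- if (output == "phylo")
      build_sim_phylo(parent[1:n_lin], birth[1:n_lin], end[1:n_lin], sampled)
    else
      recon_branching_times(parent[1:n_lin], end[1:n_lin], sampled, crown_age)
    attr(out, "n_extant") <- n_extant
    attr(out, "attempts") <- attempt
    if (output == "phylo") class(out) <- c("clade_tree", "phylo")
    return(out)
  }
  stop("rejection cap exceeded (", max_attempts, " attempts): the model ",
       "rarely produces surviving sampled crown trees; change parameters")
}

## reconstructed branching times of the sampled spanning tree, without
## building a phylo: nodes are kept lineages with >= 2 kept children, plus
## the crown itself (both crown lineages are kept by conditioning)
recon_branching_times <- function(parent, end, sampled, crown_age) {
  n <- length(parent)
  keep <- logical(n)
  for (s in sampled) {
    i <- s
    while (i > 0L && !keep[i]) { keep[i] <- TRUE; i <- parent[i] }
  }
  kept_kids <- integer(n)
  for (i in which(keep)) {
    p <- parent[i]
    if (p > 0L) kept_kids[p] <- kept_kids[p] + 1L
  }
  ages <- c(crown_age, end[keep & kept_kids >= 2L])
  new_branching_times(sort(ages, decreasing = TRUE), length(sampled))
}

## assemble the reconstructed phylo spanning the sampled lineage set
build_sim_phylo <- function(parent, birth, end, sampled) {
  n <- length(parent)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  keep <- logical(n)
  for (s in sampled) {         # mark the spanning set
    i <- s
    while (i > 0L && !keep[i]) { keep[i] <- TRUE; i <- parent[i] }
  }
  sampled_set <- logical(n); sampled_set[sampled] <- TRUE
  ## recursive newick over kept lineages, collapsing single-child chains
  desc <- function(i, top_age) {
    kids <- children[[i]]
    kids <- kids[keep[kids]]
    if (length(kids) == 0L) {
      sprintf("t%d:%.15g", i, top_age - end[i])
    } else if (length(kids) == 1L) {
      desc(kids[1L], top_age)
    } else {
      sprintf("(%s,%s):%.15g", desc(kids[1L], end[i]), desc(kids[2L], end[i]),
              top_age - end[i])
    }
  }
  ## the two crown lineages are ids 1 and 2; both are kept by conditioning
  txt <- sprintf("(%s,%s);", desc(1L, birth[1L]), desc(2L, birth[2L]))
  tree <- ape::read.tree(text = txt)
  tree
}

#' Configuration for a synthetic Neotropical-style study
#'
#' Defaults emulate the structure of the 150-clade continental compilation:
#' five taxon groups with clade counts in proportion (66, 12, 32, 24, 16);
#' a scenario mixture over the four trajectory regimes in proportion
#' (76, 30, 31, 13); log-normal crown ages clamped to 0.5-88.5 Myr with
#' mean about 30; log-normal tree sizes clamped to 7-789 tips with mean
#' about 83; Beta-distributed sampling fractions with mean about 0.57.
#'
#' @param n_clades number of clades (default 150).
#' @param group_counts named clade counts per taxon group (scaled to
#'   `n_clades`).
#' @param scenario_weights mixture over Sc1..Sc4.
#' @param age_meanlog,age_sdlog,age_range crown-age distribution (Myr).
#' @param size_meanlog,size_sdlog,size_range sampled-tip-count targets.
#' @param rho_shape Beta shape parameters for the sampling fraction.
#' @param elevation_weights named weights for elevation classes.
#' @param k_regions number of planted region blocks for the abundance
#'   table.
#' @param mixing_noise share of each clade's species outside its home
#'   block.
#' @param seed master seed (mandatory); per-clade substreams are derived
#'   from it.
#' @export
sim_config <- function(n_clades = 150L,
                       group_counts = c(plant = 66L, mammal = 12L, bird = 32L,
                                        squamate = 24L, amphibian = 16L),
                       scenario_weights = c(Sc1_gradual = 76, Sc2_exponential = 30,
                                            Sc3_saturated = 31, Sc4_waxing_waning = 13),
                       age_meanlog = log(29.9) - 0.75^2 / 2, age_sdlog = 0.75,
                       age_range = c(0.5, 88.5),
                       size_meanlog = log(83.4) - 0.5, size_sdlog = 1,
                       size_range = c(7, 789),
                       rho_shape = c(2.65, 2),
                       elevation_weights = c(lowland = 42, montane = 8,
                                             highland = 6, mixed = 94),
                       k_regions = 4L, mixing_noise = 0.1, seed = 1L) {
  stopifnot(!is.null(seed))
  list(n_clades = as.integer(n_clades), group_counts = group_counts,
       scenario_weights = scenario_weights / sum(scenario_weights),
       age_meanlog = age_meanlog, age_sdlog = age_sdlog,
       age_range = age_range, size_meanlog = size_meanlog,
       size_sdlog = size_sdlog, size_range = size_range,
       rho_shape = rho_shape,
       elevation_weights = elevation_weights / sum(elevation_weights),
       k_regions = as.integer(k_regions), mixing_noise = mixing_noise,
       seed = as.integer(seed))
}

## scenario-specific generating parameters hitting an expected sampled
## richness of n_target at crown age T (via int r dt = log(n/(2 rho)))
scenario_params <- function(scenario, T, n_target, rho) {
  G <- max(log(n_target / (2 * rho)), 0.1)
  switch(scenario,
    Sc1_gradual = {
      l0 <- (G / T) / 0.8          # turnover mu0 = 0.2 lambda0
      list(lambda0 = l0, mu0 = 0.2 * l0, alpha = 0)
    },
    Sc2_exponential = {
      a <- -1.0 / T                # speciation increasing towards present
      s <- (exp(a * T) - 1) / a
      l0 <- G / (0.8 * s)
      list(lambda0 = l0, mu0 = 0.2 * l0 * s / T, alpha = a)
    },
    Sc3_saturated = {
      a <- 1.2 / T                 # decreasing towards present, r(0) > 0
      s <- (exp(a * T) - 1) / a
      l0 <- G / (s - 0.6 * T)
      list(lambda0 = l0, mu0 = 0.6 * l0, alpha = a)
    },
    Sc4_waxing_waning = {
      a <- 1.6 / T                 # decreasing, r(0) < 0
      s <- (exp(a * T) - 1) / a
      l0 <- G / (s - 1.3 * T)
      list(lambda0 = l0, mu0 = 1.3 * l0, alpha = a)
    })
}

#' Simulate a whole synthetic study
#'
#' Generates `n_clades` trees under per-scenario birth-death regimes
#' (Sc1: constant rates; Sc2: speciation increasing towards the present;
#' Sc3: speciation decreasing, present-day diversification non-negative;
#' Sc4: speciation decreasing with extinction exceeding speciation at
#' present), together with clade metadata, a planted clade-by-region
#' abundance table, and the true generating parameters for recovery
#' scoring.  Deterministic for a fixed seed (per-clade RNG substreams).
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_study`: list with `records`
#'   (data.frame incl. region counts), `trees`, `truth`, `abundance`,
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  n <- config$n_clades
  groups <- rep(names(config$group_counts),
                round(config$group_counts / sum(config$group_counts) * n))
  groups <- c(groups, rep(names(config$group_counts)[1L],
                          max(0, n - length(groups))))[seq_len(n)]
  set.seed(config$seed)
  scenario <- sample(names(config$scenario_weights), n, replace = TRUE,
                     prob = config$scenario_weights)
  elev <- sample(names(config$elevation_weights), n, replace = TRUE,
                 prob = config$elevation_weights)

  trees <- vector("list", n)
  truth <- vector("list", n)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(config$seed + 7919L * i)  # per-clade substream
    for (try in 1:50) {
      T <- min(max(stats::rlnorm(1, config$age_meanlog, config$age_sdlog),
                   config$age_range[1]), config$age_range[2])
      n_target <- min(max(stats::rlnorm(1, config$size_meanlog,
                                        config$size_sdlog),
                          config$size_range[1]), config$size_range[2])
      rho <- min(max(stats::rbeta(1, config$rho_shape[1], config$rho_shape[2]),
                     0.05), 1)
      par <- scenario_params(scenario[i], T, n_target, rho)
      if (par$lambda0 <= 0 || par$lambda0 > 10) next
      lam <- rate_spec("speciation", if (par$alpha == 0) "constant"
                       else "exp_time", par$lambda0, par$alpha)
      mu <- rate_spec("extinction", "constant", par$mu0)
      tree <- tryCatch(
        simulate_tree(lam, mu, T, rho, max_attempts = 200L,
                      max_lineages = 20000L),
        error = function(e) NULL)
      if (is.null(tree) || ape::Ntip(tree) < 4L) next
      ## keep the realized size near its drawn target so the study-level
      ## size distribution tracks the configured one (realized birth-death
      ## sizes are geometric-tailed around the expectation otherwise)
      ## accept realized sizes near the drawn target and inside the
      ## configured size range, so the study-level size distribution
      ## tracks the configured one (realized birth-death sizes are
      ## heavy-tailed around the expectation otherwise)
      nt <- ape::Ntip(tree)
      lo <- max(config$size_range[1], 0.5 * n_target)
      hi <- min(config$size_range[2], 1.6 * n_target)
      if (nt < lo || nt > hi) next
      trees[[i]] <- tree
      truth[[i]] <- data.frame(clade_id = sprintf("clade_%03d", i),
                               scenario = scenario[i],
                               lambda0 = par$lambda0, mu0 = par$mu0,
                               alpha = par$alpha, beta = 0,
                               crown_age = T, rho_drawn = rho)
      n_desc <- attr(tree, "n_extant")
      rec[[i]] <- data.frame(clade_id = sprintf("clade_%03d", i),
                             taxon_group = groups[i],
                             n_sampled = ape::Ntip(tree),
                             n_described = n_desc,
                             sampling_fraction = ape::Ntip(tree) / n_desc,
                             crown_age = max(ape::branching.times(tree)),
                             elevation_class = elev[i])
      break
    }
    if (is.null(trees[[i]]))
      stop("could not generate clade ", i, " under scenario ", scenario[i])
  }
  records <- do.call(rbind, rec)
  truth <- do.call(rbind, truth)

  abundance <- simulate_abundance(n_clades = n, k_true = config$k_regions,
                                  mixing_noise = config$mixing_noise,
                                  seed = config$seed + 999L,
                                  totals = records$n_described)
  rownames(abundance) <- records$clade_id
  records <- cbind(records, as.data.frame(abundance))
  structure(list(records = records, trees = stats::setNames(trees, records$clade_id),
                 truth = truth, abundance = abundance, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study: %d clades (seed %d)\n",
                     "  tips: mean %.1f [%d-%d]; crown age: mean %.1f Myr; ",
                     "rho: mean %.2f\n"),
              nrow(x$records), x$config$seed, mean(x$records$n_sampled),
              min(x$records$n_sampled), max(x$records$n_sampled),
              mean(x$records$crown_age), mean(x$records$sampling_fraction)))
  print(table(x$truth$scenario))
  invisible(x)
}

#' Simulate a clade-by-region abundance matrix with planted structure
#'
#' Regions are partitioned into `k_true` blocks; each clade concentrates
#' `1 - mixing_noise` of its species (in expectation) in one home block
#' and spreads the rest uniformly over the other regions.
#'
#' @param n_clades number of clade rows.
#' @param n_regions number of regions (default 13, named per
#'   [neotropical_regions()]).
#' @param k_true number of planted blocks (<= n_regions).
#' @param mixing_noise expected off-block share in `[0, 1)`.
#' @param seed RNG seed.
#' @param totals optional per-clade species totals (default log-normal,
#'   mean about 80).
#' @return an abundance matrix with attribute `block` (the planted
#'   region-to-block map).
#' @export
simulate_abundance <- function(n_clades, n_regions = 13L, k_true = 5L,
                               mixing_noise = 0.05, seed = 1L,
                               totals = NULL) {
  if (k_true > n_regions) stop("k_true cannot exceed n_regions")
  set.seed(seed)
  region_names <- if (n_regions == 13L) neotropical_regions()
                  else paste0("region_", seq_len(n_regions))
  block <- sort(rep_len(seq_len(k_true), n_regions))
  if (is.null(totals))
    totals <- pmax(5, round(stats::rlnorm(n_clades, log(80) - 0.32, 0.8)))
  home <- rep_len(seq_len(k_true), n_clades)
  m <- matrix(0L, n_clades, n_regions,
              dimnames = list(sprintf("clade_%03d", seq_len(n_clades)),
                              region_names))
  for (i in seq_len(n_clades)) {
    p <- rep(0, n_regions)
    in_home <- block == home[i]
    p[in_home] <- (1 - mixing_noise) / sum(in_home)
    if (mixing_noise > 0 && any(!in_home))
      p[!in_home] <- mixing_noise / sum(!in_home)
    m[i, ] <- stats::rmultinom(1L, totals[i], p)
  }
  attr(m, "block") <- stats::setNames(block, region_names)
  attr(m, "home") <- home
  m
}

#' Score scenario and parameter recovery on a synthetic study
#'
#' @param study a [simulate_study()] result.
#' @param calls a character vector (or list of `scenario_call`s) of called
#'   scenarios, one per clade, in `study` order.
#' @param params optional data.frame of fitted `lambda0`, `mu0` per clade
#'   for relative-error scoring.
#' @return list with `confusion` (true x called matrix), `accuracy`, and
#'   `param_errors` (relative errors, when `params` given).
#' @export
score_recovery <- function(study, calls, params = NULL) {
  if (is.list(calls))
    calls <- vapply(calls, function(x) x$scenario, "")
  lev <- c("Sc1_gradual", "Sc2_exponential", "Sc3_saturated",
           "Sc4_waxing_waning")
  confusion <- table(true = factor(study$truth$scenario, lev),
                     called = factor(calls, lev))
  out <- list(confusion = confusion,
              accuracy = sum(diag(confusion)) / sum(confusion))
  if (!is.null(params)) {
    out$param_errors <- data.frame(
      lambda0_rel = (params$lambda0 - study$truth$lambda0) / study$truth$lambda0,
      mu0_rel = (params$mu0 - study$truth$mu0) / study$truth$mu0)
  }
  out
}
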