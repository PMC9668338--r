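## Independent oracles used across the suite.  These are deliberately coded
## from closed forms / brute force, not through the package's numerical path.

## Constant-rate reconstructed likelihood with sampling, conditioned on the
## crown age and survival of both crown lineages (closed forms for the
## no-sampled-descendant and one-sampled-descendant probabilities).
oracle_p0 <- function(t, l, m, r) {
  1 - r * (l - m) / (r * l + (l * (1 - r) - m) * exp(-(l - m) * t))
}
oracle_p1 <- function(t, l, m, r) {
  r * (l - m)^2 * exp(-(l - m) * t) /
    (r * l + (l * (1 - r) - m) * exp(-(l - m) * t))^2
}
oracle_const_loglik <- function(ages, l, m, r = 1) {
  t1 <- ages[1]; ev <- ages[-1]
  2 * log(oracle_p1(t1, l, m, r)) - 2 * log(1 - oracle_p0(t1, l, m, r)) +
    sum(log(l) + log(oracle_p1(ev, l, m, r)))
}

## Yule crown likelihood by interval-by-interval exposure accounting
oracle_yule_loglik <- function(ages, l) {
  t1 <- ages[1]; ev <- ages[-1]
  sum(log(l) - l * ev) - 2 * l * t1
}

## Brute-force two-sided Fisher p for a 2x2 table: enumerate all tables
## with the observed margins, sum probabilities <= observed
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- stats::dhyper(ks, r1, n - r1, c1)
  obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

## Morisita-Horn dissimilarity straight from the definition
oracle_mh <- function(a, b) {
  A <- sum(a); B <- sum(b)
  1 - 2 * sum(a * b) / ((sum(a^2) / A^2 + sum(b^2) / B^2) * A * B)
}

## Benjamini-Hochberg from the definition (step-up)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj, 1)[order(o)]
}

## All clades of a tree as tip-label sets (for brute-force enumeration)
all_clade_tipsets <- function(tree) {
  ntip <- ape::Ntip(tree)
  lapply((ntip + 1):(ntip + tree$Nnode), function(nd) {
    sort(ape::extract.clade(tree, nd)$tip.label)
  })
}

## default synthetic curves shared by battery tests
test_curves <- function() {
  list(temperature = fit_smooth(make_synthetic_curve("cooling_ramp")),
       uplift = fit_smooth(make_synthetic_curve(
         "cooling_ramp", max_age = 80, value_range = c(0, 4000),
         units = "m", label = "uplift")))
}

## construct a bd_fit stub for classifier tests (no optimization involved)
stub_fit <- function(lambda0, mu0, alpha = 0, beta = 0, crown_age = 20,
                     lambda_form = if (alpha != 0) "exp_time" else "constant",
                     mu_form = if (beta != 0) "exp_time" else "constant",
                     name = "stub", family = "time", converged = TRUE) {
  free <- c("lambda0", "mu0",
            if (lambda_form != "constant") "alpha",
            if (mu_form != "constant") "beta")
  par <- c(lambda0 = lambda0, mu0 = mu0)
  if ("alpha" %in% free) par <- c(par, alpha = alpha)
  if ("beta" %in% free) par <- c(par, beta = beta)
  structure(list(model_name = name, family = family,
                 template = list(name = name, family = family,
                                 lambda_form = lambda_form, mu_form = mu_form,
                                 env = NULL, free = free, k = length(free)),
                 mle_params = par, max_loglik = 0, k = length(free),
                 n = 50L, AICc = 0, converged = converged,
                 crown_age = crown_age, rho = 1),
            class = "bd_fit")
}
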