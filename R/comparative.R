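## Cross-tabulation and phylogenetic-signal statistics used to compare
## diversity trajectories and rates across taxa, bioregions, elevations,
## and environmental drivers.  Resampling tests are seed-deterministic.

new_div_test <- function(method, statistic = NA_real_, df = NA_real_, p,
                         seed = NA_integer_, n_draws = NA_integer_,
                         extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df, p = p,
                   seed = seed, n_draws = n_draws), extra),
            class = "div_test")
}

#' @export
print.div_test <- function(x, ...) {
  cat(sprintf("%s: %sp = %.4g%s\n", x$method,
              if (is.na(x$statistic)) "" else
                sprintf("statistic = %.4g, ", x$statistic),
              x$p,
              if (is.na(x$n_draws)) "" else
                sprintf(" (%d draws, seed %d)", x$n_draws, x$seed)))
  invisible(x)
}

#' Fisher's exact test on a contingency table
#'
#' 2x2 tables are tested exactly (two-sided, summing hypergeometric tables
#' with probability at most the observed); larger tables use a seeded
#' Monte-Carlo p over `n_draws` tables sampled with fixed margins.  A zero
#' row or column margin makes the table degenerate: p = 1.
#'
#' @param tab matrix of non-negative integer counts, at least 2x2.
#' @param n_draws Monte-Carlo draws for r x c tables (default 1e5).
#' @param seed RNG seed for the Monte-Carlo path.
#' @return a `div_test` (with `degenerate = TRUE` when a margin is zero).
#' @export
fisher_exact <- function(tab, n_draws = 1e5L, seed = 1L) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be integers >= 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(new_div_test("fisher_exact", p = 1, extra = list(degenerate = TRUE)))
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    p <- stats::fisher.test(tab)$p.value
    return(new_div_test("fisher_exact", p = min(p, 1)))
  }
  set.seed(seed)
  p <- stats::fisher.test(tab, simulate.p.value = TRUE,
                          B = as.integer(n_draws))$p.value
  new_div_test("fisher_exact_mc", p = p, seed = seed,
               n_draws = as.integer(n_draws))
}

#' Pairwise Fisher tests with multiple-testing correction
#'
#' Tests all pairs of levels on one margin of the table (2 x c sub-tables)
#' and adjusts the p values by Benjamini-Hochberg.
#'
#' @param tab contingency table; pairs are formed over `margin` (1 = rows).
#' @param correction p-adjustment method (default `"BH"`).
#' @inheritParams fisher_exact
#' @return data.frame with one row per pair: `a`, `b`, `p`, `adjusted_p`.
#' @export
pairwise_fisher <- function(tab, margin = 1L, correction = "BH",
                            n_draws = 1e5L, seed = 1L) {
  tab <- as.matrix(tab)
  if (margin == 2L) tab <- t(tab)
  lev <- rownames(tab) %||% as.character(seq_len(nrow(tab)))
  pairs <- utils::combn(nrow(tab), 2L)
  p <- apply(pairs, 2L, function(ij) {
    sub <- tab[ij, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    if (ncol(sub) < 2L || any(rowSums(sub) == 0)) return(1)
    fisher_exact(sub, n_draws = n_draws, seed = seed)$p
  })
  adj <- if (nrow(tab) > 2L) stats::p.adjust(p, method = correction) else p
  data.frame(a = lev[pairs[1L, ]], b = lev[pairs[2L, ]],
             p = p, adjusted_p = adj, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared reference on
#' `(groups - 1)` degrees of freedom.
#'
#' @param values numeric vector, or a list of per-group vectors.
#' @param groups group labels (ignored when `values` is a list).
#' @return a `div_test` with `statistic` = H.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  if (length(unique(values)) < 2L)
    stop("Kruskal-Wallis statistic undefined: all values identical")
  kt <- stats::kruskal.test(values, factor(groups))
  new_div_test("kruskal_wallis", statistic = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value)
}

#' Blomberg's K for a continuous trait on a tree
#'
#' Ratio of the observed to the Brownian-expected mean-squared-error
#' contrast, with a permutation p from tip-label shuffles (K near 1 under
#' Brownian motion; near 0 for phylogenetically random traits).
#'
#' @param tree an ultrametric `phylo`.
#' @param trait named numeric vector over all tips.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return a `div_test` with `statistic` = K.
#' @export
blomberg_K <- function(tree, trait, n_perm = 999L, seed = 1L) {
  if (is.null(names(trait))) names(trait) <- tree$tip.label
  if (!all(tree$tip.label %in% names(trait)))
    stop("trait must be defined for every tip")
  trait <- trait[tree$tip.label]
  if (stats::var(trait) == 0) stop("trait has zero variance")
  set.seed(seed)
  ps <- phytools::phylosig(tree, trait, method = "K", test = TRUE,
                           nsim = n_perm)
  new_div_test("blomberg_K", statistic = unname(ps$K), p = unname(ps$P),
               seed = seed, n_draws = as.integer(n_perm))
}

#' Delta statistic for phylogenetic signal of a categorical trait
#'
#' Measures how concentrated the marginal ancestral-state probabilities
#' are: states are reconstructed under an equal-rates Markov model by
#' maximum likelihood, each internal node gets the Shannon entropy of its
#' marginal probabilities, and delta aggregates the mean information gain
#' `log(n_states) - mean(entropy)` (larger = stronger signal; delta is
#' unbounded above).  Significance is the fraction of `n_rand` tip-label
#' randomizations with delta at least the observed value.
#'
#' @param tree an ultrametric `phylo`.
#' @param trait named character/factor over all tips, >= 2 categories
#'   each with >= 2 tips.
#' @param n_rand randomizations (default 99).
#' @param seed RNG seed.
#' @return a `div_test` with `statistic` = delta.
#' @export
delta_stat <- function(tree, trait, n_rand = 99L, seed = 1L) {
  if (is.null(names(trait))) names(trait) <- tree$tip.label
  trait <- as.character(trait[tree$tip.label])
  lev <- unique(trait)
  if (length(lev) < 2L) stop("trait must have at least 2 categories")
  if (any(table(trait) < 2L)) stop("each category needs at least 2 tips")
  obs <- delta_value(tree, trait)
  set.seed(seed)
  null <- vapply(seq_len(n_rand), function(i) {
    delta_value(tree, sample(trait))
  }, 0)
  p <- (1 + sum(null >= obs)) / (n_rand + 1)
  new_div_test("delta_stat", statistic = obs, p = p, seed = seed,
               n_draws = as.integer(n_rand),
               extra = list(null = null))
}

## mean per-node information gain from ML marginal ancestral states (ER model)
delta_value <- function(tree, trait) {
  fit <- tryCatch(
    ape::ace(factor(trait), tree, type = "discrete", model = "ER"),
    error = function(e) NULL)
  k <- length(unique(trait))
  if (is.null(fit)) return(0)
  pr <- pmax(fit$lik.anc, 1e-12)
  pr <- pr / rowSums(pr)
  ent <- -rowSums(pr * log(pr))
  log(k) - mean(ent)
}

#' Phylogenetic ANOVA with Brownian-simulation null
#'
#' Standard ANOVA F for a continuous response across groups, with the null
#' distribution obtained from Brownian-motion simulations on the tree
#' (variance estimated from the data) and Holm-adjusted post hoc pairwise
#' comparisons against the same simulated null.
#'
#' @param tree `phylo` with one tip per observation.
#' @param group named factor over tips (groups with < 2 members are
#'   excluded with a warning).
#' @param response named numeric over tips.
#' @param n_sim Brownian simulations (default 1000).
#' @param seed RNG seed.
#' @return a `div_test` with `statistic` = F and a `posthoc` matrix of
#'   adjusted pairwise p values.
#' @export
phylo_anova <- function(tree, group, response, n_sim = 1000L, seed = 1L) {
  if (is.null(names(group))) names(group) <- tree$tip.label
  if (is.null(names(response))) names(response) <- tree$tip.label
  group <- factor(as.character(group[tree$tip.label]))
  response <- response[tree$tip.label]
  small <- names(table(group))[table(group) < 2L]
  if (length(small) > 0L) {
    warning("excluding group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    tree <- ape::keep.tip(tree, tree$tip.label[keep])
    group <- droplevels(group[keep])
    response <- response[tree$tip.label]
  }
  if (nlevels(group) < 2L) stop("need at least 2 usable groups")
  set.seed(seed)
  utils::capture.output(
    pa <- phytools::phylANOVA(tree, stats::setNames(group, tree$tip.label),
                              response, nsim = n_sim, posthoc = TRUE,
                              p.adj = "holm"))
  new_div_test("phylo_anova", statistic = pa$F, p = pa$Pf, seed = seed,
               n_draws = as.integer(n_sim),
               extra = list(posthoc = pa$Pt))
}
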