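# neodiv

Diversification trajectories, pulled rates, and macroevolutionary
bioregions for Neotropical clades.

## What this package is for

Comparative studies of continental diversification ask, for each of many
time-calibrated clade phylogenies: did diversity expand gradually, expand
exponentially, saturate, or wax and wane?  Was rate variation driven by
time, by paleotemperature, or by Andean uplift?  And do the answers differ
across taxa, bioregions, or elevations?  `neodiv` implements that whole
workflow for users with a battery of ultrametric trees (newick), per-clade
metadata (described richness, sampling fraction, taxon group, elevation
class), paleoenvironmental curves (age/value tables), and clade-by-region
species counts — plus simulators that generate all of these with known
truths, so every stage is testable without any downloads.

## The models at the core

Each clade is a reconstructed birth-death process with speciation rate
λ(t) and extinction rate μ(t) (t = Myr before present) and uniform species
sampling ρ.  Rates are constant, exponential in time
(λ(t) = λ₀e^(αt); α > 0 means rates decreasing towards the present), or
exponential in an environmental curve (λ(t) = λ₀e^(αE(t))).  The
likelihood of the branching times, conditioned on crown age and survival
of both crown lineages, is maximized for a 10-model battery (constant;
λ(t)/μ(t)/both; the same for temperature and uplift curves), ranked by
AICc with Akaike weights.  The winner's net rate r(t) = λ(t) − μ(t) maps
the clade to one of four scenarios: Sc1 gradual (r constant), Sc2
exponential (r increasing towards the present), Sc3 saturated
(r decreasing, r(0) ≥ 0), Sc4 waxing-and-waning (r decreasing, r(0) < 0).

Because canonical rates are not identifiable from extant trees alone, the
same clades are re-analysed with pulled diversification rates: the
identifiable pair (r_p(t) = λ − μ + λ′/λ, ρλ₀) is fitted on an age grid
(constant vs 3-interval models, AIC selection), and a negative present-day
pulled extinction rate μ_p(0) = λ₀ − r_p(0) diagnoses currently decreasing
speciation.  Bioregions are derived from clade×region abundance tables by
Hellinger transformation, Morisita-Horn dissimilarity, MDS embedding, and
K-means with elbow selection; trajectories and rates are then compared
across groups with Fisher exact tests (BH-corrected pairwise),
Kruskal-Wallis tests, Blomberg's K, a categorical δ-statistic, and
phylogenetic ANOVA.

## Worked example

```r
library(neodiv)

## a synthetic clade evolving at constant rates (gradual-expansion regime)
lam <- rate_spec("speciation", "constant", 0.25)   # events/lineage/Myr
mu  <- rate_spec("extinction", "constant", 0.08)
tree <- simulate_tree(lam, mu, crown_age = 18, rho = 0.8, seed = 3)
ape::Ntip(tree)
#> [1] 117

curves <- list(
  temperature = fit_smooth(make_synthetic_curve("cooling_ramp")),
  uplift = fit_smooth(make_synthetic_curve("cooling_ramp", max_age = 80,
                      value_range = c(0, 4000), units = "m", label = "uplift")))

bat <- fit_battery(branching_times(tree), rho = 0.8, curves = curves,
                   settings = fit_settings(n_restarts = 5, seed = 1))
bat$best
#> Birth-death fit 'constant' (117 tips, rho = 0.8)
#>   params: lambda0 = 0.315, mu0 = 0.08518
#>   logLik = -278.5895, k = 2, AICc = 561.2842, converged = TRUE
classify_scenario(bat$best)
#> Scenario Sc1_gradual (speciation constant, r(0) = 0.2299)

pdr <- fit_pdr_battery(branching_times(tree), rho = 0.8,
                       settings = fit_settings(n_restarts = 20, seed = 2))
pdr
#> Pulled-rate fit: 1 interval(s), logLik = -258.4853, AIC = 520.9705
#>   knots (Myr): 0, 10.7
#>   r_p:          0.2076, 0.2076
#>   rho*lambda0 = 0.2619, lambda0 = 0.3274, mu_p(0) = 0.1198
#> Pulled speciation trend: constant (mu_p(0) = 0.1198)
```

The 10-model battery selects the constant model and classifies the clade
as a gradual expansion, with the fitted rates near the generating values
(true λ₀ = 0.25, μ₀ = 0.08 — extinction is recovered closely, speciation
with the upward scatter typical of single trees this size).  The pulled
analysis independently selects the constant-r_p model, with
r̂_p = 0.208 close to the true net rate r = 0.17 and a non-negative
present-day pulled extinction rate, i.e. no evidence of decreasing
speciation.  The pulled fit is restricted to the time span with more than
10 lineages (here the youngest 10.7 Myr of the 18 Myr history).

Study-level synthesis works the same way from a `simulate_study()` (or
from real tables read with `read_clade_table()` / `load_env_table()`):
fit per-clade batteries, collect `classify_scenario()` calls, and tabulate
with `aggregate_counts()`, `sensitivity_filter()`, and
`tally_second_best()`; derive bioregions with
`hellinger_rows() |> morisita_horn() |> embed_and_cluster()` and
`assign_clades()`.

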