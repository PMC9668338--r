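#' Percentage with half-up rounding at a fixed precision
#'
#' `100 * count / total`, rounded half-up (not banker's rounding) to
#' `digits` decimals, as printed in summary tables; counts should always
#' be reported alongside.
#'
#' @param count numerator (0 <= count <= total).
#' @param total denominator (> 0).
#' @param digits decimals (default 0).
#' @export
percent <- function(count, total, digits = 0L) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(count < 0) || any(count > total)) stop("need 0 <= count <= total")
  x <- 100 * count / total
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Pooled taxon super-groups
#'
#' Tetrapods = mammal + bird + squamate + amphibian; endotherms = mammal +
#' bird; ectotherms = squamate + amphibian.
#' @param taxon_group character vector of group labels.
#' @param pooling `"plant_tetrapod"` or `"thermy"`.
#' @export
pool_taxa <- function(taxon_group, pooling = c("plant_tetrapod", "thermy")) {
  pooling <- match.arg(pooling)
  tet <- c("mammal", "bird", "squamate", "amphibian")
  if (pooling == "plant_tetrapod") {
    ifelse(taxon_group == "plant", "plant",
           ifelse(taxon_group %in% tet, "tetrapod", NA))
  } else {
    ifelse(taxon_group == "plant", "plant",
           ifelse(taxon_group %in% c("mammal", "bird"), "endotherm",
                  ifelse(taxon_group %in% c("squamate", "amphibian"),
                         "ectotherm", NA)))
  }
}

#' Aggregate scenario calls into study-level summary tables
#'
#' Cross-tabulates scenario calls against taxon groups (with
#' plant/tetrapod and endotherm/ectotherm pooling), driver classes, and
#' optionally bioregion clusters.  Clades without a call are tallied in an
#' `"unclassified"` bucket, never dropped.
#'
#' @param calls character vector of scenario labels (or list of
#'   `scenario_call`s), one per clade; `NA` allowed.
#' @param records clade metadata data.frame with `taxon_group` (and
#'   optionally `clade_id`).
#' @param clusters optional cluster labels per clade.
#' @param drivers optional driver-class labels per clade (constant/time/
#'   temperature/uplift).
#' @return an object of class `study_summary`: list of contingency tables
#'   plus percentage tables (counts always retained).
#' @export
aggregate_counts <- function(calls, records, clusters = NULL, drivers = NULL) {
  if (is.list(calls))
    calls <- vapply(calls, function(x) if (is.null(x)) NA_character_
                    else x$scenario, "")
  calls[is.na(calls)] <- "unclassified"
  n <- length(calls)
  stopifnot(nrow(records) == n)
  out <- list(n_clades = n)
  out$by_scenario <- table(scenario = calls)
  out$pct_scenario <- percent(as.integer(out$by_scenario), n, 1L)
  names(out$pct_scenario) <- names(out$by_scenario)
  out$scenario_by_group <- table(scenario = calls,
                                 group = records$taxon_group)
  out$scenario_by_pool <- table(scenario = calls,
                                pool = pool_taxa(records$taxon_group))
  out$scenario_by_thermy <- table(scenario = calls,
                                  pool = pool_taxa(records$taxon_group,
                                                   "thermy"))
  if (!is.null(drivers)) {
    out$by_driver <- table(driver = drivers)
    out$scenario_by_driver <- table(scenario = calls, driver = drivers)
  }
  if (!is.null(clusters))
    out$scenario_by_cluster <- table(scenario = calls, cluster = clusters)
  class(out) <- "study_summary"
  out
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("Study summary over %d clades\n", x$n_clades))
  tab <- rbind(count = as.integer(x$by_scenario), percent = x$pct_scenario)
  colnames(tab) <- names(x$by_scenario)
  print(tab)
  invisible(x)
}

#' Sensitivity filters on the clade battery
#'
#' Strict exclusion filters: `min_tips_20` keeps clades with at least 20
#' sampled species (excluding "<20 species" trees); `min_sampling_0.2`
#' keeps clades with sampling fraction at least 0.2 (excluding "<20%
#' sampled" trees).
#'
#' @param records clade metadata with `n_sampled` and `sampling_fraction`.
#' @param rule `"min_tips_20"` or `"min_sampling_0.2"`.
#' @return logical keep vector.
#' @export
sensitivity_filter <- function(records, rule = c("min_tips_20",
                                                 "min_sampling_0.2")) {
  rule <- match.arg(rule)
  if (rule == "min_tips_20") records$n_sampled >= 20
  else records$sampling_fraction >= 0.2
}

#' Driver-class tallies for best and second-best battery models
#'
#' @param batteries list of [fit_battery()] results.
#' @return matrix with rows `rank1`, `rank2` and one column per driver
#'   class present.
#' @export
tally_second_best <- function(batteries) {
  fam1 <- vapply(batteries, function(b) b$best$family, "")
  fam2 <- vapply(batteries, function(b) b$second_best$family, "")
  lev <- c("constant", "time", "temperature", "uplift")
  rbind(rank1 = table(factor(fam1, lev)),
        rank2 = table(factor(fam2, lev)))
}
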