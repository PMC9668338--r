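#' Read a clade metadata table
#'
#' CSV with header `clade_id, taxon_group, n_sampled, n_described,
#' elevation_class` plus the 13 fixed region-count columns.  Validates the
#' taxon/elevation vocabularies and the sampling fractions.
#'
#' @param path CSV file.
#' @return data.frame with an added `sampling_fraction` column.
#' @export
read_clade_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clade_id", "taxon_group", "n_sampled", "n_described",
            "elevation_class", neotropical_regions())
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(d$taxon_group,
                 c("plant", "mammal", "bird", "squamate", "amphibian"))
  if (length(bad) > 0L) stop("unknown taxon group(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(d$elevation_class,
                 c("lowland", "montane", "highland", "mixed"))
  if (length(bad) > 0L)
    stop("unknown elevation class(es): ", paste(bad, collapse = ", "))
  if (any(d$n_sampled > d$n_described))
    stop("n_sampled exceeds n_described for some clades (rho must be <= 1)")
  d$sampling_fraction <- d$n_sampled / d$n_described
  d
}

#' Write a clade metadata table (the format [read_clade_table()] reads)
#'
#' @param records data.frame as produced by [simulate_study()].
#' @param path output CSV path.
#' @export
write_clade_table <- function(records, path) {
  cols <- c("clade_id", "taxon_group", "n_sampled", "n_described",
            "elevation_class", neotropical_regions())
  utils::write.csv(records[, cols], path, row.names = FALSE)
}

#' Serialize a battery selection table to a data.frame/CSV
#'
#' @param battery a [fit_battery()] result.
#' @param path optional CSV path; when `NULL` the data.frame is returned
#'   only.
#' @export
write_selection_table <- function(battery, path = NULL) {
  tab <- battery$table
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Published clade counts used for desk-scale arithmetic checks
#'
#' Printed tallies from the 150-clade continental Neotropical compilation
#' (clades per taxon group; species per group; scenario support under the
#' time-only and environment-inclusive model comparisons; pulled-rate
#' tallies; driver-class tallies).  These are inputs for reproducing the
#' published percentages from their counts, not outputs of this package.
#'
#' @return a nested list of integer counts.
#' @export
published_counts <- function() {
  list(
    n_clades = 150L,
    n_species = c(plant = 6222L, mammal = 922L, bird = 2216L,
                  squamate = 1148L, amphibian = 2004L),
    clades_per_group = c(plant = 66L, mammal = 12L, bird = 32L,
                         squamate = 24L, amphibian = 16L),
    ## best-fit counts: constant vs time-variable comparison only
    cdr_time_only = c(Sc1 = 101L, Sc2 = 20L, Sc3 = 24L, Sc4 = 5L),
    ## counts when environmental models are included
    cdr_env = c(Sc1 = 76L, Sc2 = 30L, Sc3 = 31L, Sc4 = 13L),
    ## among the 49 time-variable trees (time-only comparison)
    time_variable_speciation = c(decreasing = 28L, increasing = 12L,
                                 constant = 9L),
    ## pulled-rate comparison
    pdr = c(constant = 95L, variable = 55L, mu_p0_negative = 51L),
    ## driver classes under the environment-inclusive comparison
    drivers = c(constant = 76L, time = 17L, temperature = 40L, uplift = 17L),
    ## sensitivity-filter survivors
    filters = c(min_tips_20 = 99L, min_sampling_0.2 = 137L))
}
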