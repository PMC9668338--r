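#' Parse and validate an ultrametric, time-calibrated tree
#'
#' Reads a rooted newick string with branch lengths (Myr) and checks that it
#' satisfies the assumptions of the diversification likelihoods: at least two
#' tips, bifurcating topology, non-negative edge lengths, and all root-to-tip
#' path lengths equal within a relative tolerance of the crown age.
#'
#' Polytomies are rejected by default.  With `resolve_polytomies = TRUE` they
#' are resolved into zero-length bifurcations (with a warning), which leaves
#' branching times unchanged.
#'
#' @param text a newick string, or an [ape::phylo] object to validate.
#' @param resolve_polytomies logical; resolve multifurcations to zero-length
#'   bifurcations instead of failing.
#' @param tol relative ultrametricity tolerance, as a fraction of crown age.
#' @return a validated `phylo` object (class `c("clade_tree", "phylo")`).
#' @export
parse_newick <- function(text, resolve_polytomies = FALSE, tol = 1e-6) {
  if (inherits(text, "phylo")) {
    tree <- text
  } else {
    if (!is.character(text) || length(text) != 1L)
      stop("`text` must be a single newick string or a phylo object")
    tree <- tryCatch(ape::read.tree(text = text),
                     error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tree))
      stop("malformed newick string: ", substr(text, 1L, 60L))
  }
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (ape::Ntip(tree) < 2L)
    stop("tree must have at least 2 tips")
  if (any(tree$edge.length < 0))
    stop("tree has negative edge lengths")
  if (!ape::is.binary(tree)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies; set resolve_polytomies = TRUE to ",
           "resolve them to zero-length bifurcations")
    warning("resolving polytomies to zero-length bifurcations")
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  depths <- node_depths(tree)
  tip_depth <- depths[seq_len(ape::Ntip(tree))]
  crown <- max(tip_depth)
  if (crown <= 0) stop("crown age must be positive")
  dev <- abs(tip_depth - crown)
  if (max(dev) > tol * crown) {
    worst <- tree$tip.label[which.max(dev)]
    stop(sprintf(
      "tree is not ultrametric: tip '%s' deviates by %.3g Myr (tolerance %.3g)",
      worst, max(dev), tol * crown))
  }
  class(tree) <- c("clade_tree", "phylo")
  tree
}

## root-to-node path lengths, indexed by node id
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  depths <- numeric(n_node)
  ## edges in preorder so parents are visited first
  ord <- order(tree$edge[, 1L])
  root <- ape::Ntip(tree) + 1L
  depths[root] <- 0
  for (i in ord) {
    p <- tree$edge[i, 1L]
    c <- tree$edge[i, 2L]
    depths[c] <- depths[p] + tree$edge.length[i]
  }
  depths
}

#' Branching times of an ultrametric tree
#'
#' Node ages (Myr before present) sorted in descending order; the first
#' element is the crown age and the vector has `n_tips - 1` entries.
#'
#' @param tree a validated ultrametric tree ([parse_newick]) or a `phylo`.
#' @return an object of class `branching_times`: a list with `ages`
#'   (descending) and `n_tips`.
#' @export
branching_times <- function(tree) {
  if (inherits(tree, "branching_times")) return(tree)
  if (!inherits(tree, "clade_tree")) tree <- parse_newick(tree)
  ages <- sort(unname(ape::branching.times(tree)), decreasing = TRUE)
  new_branching_times(ages, ape::Ntip(tree))
}

#' Construct branching times from a vector of node ages
#'
#' @param ages node ages in Myr before present (any order).
#' @param n_tips number of tips; defaults to `length(ages) + 1`.
#' @return an object of class `branching_times`.
#' @export
new_branching_times <- function(ages, n_tips = length(ages) + 1L) {
  ages <- sort(as.numeric(ages), decreasing = TRUE)
  if (length(ages) != n_tips - 1L)
    stop("need n_tips - 1 branching times")
  if (any(ages <= 0) || any(!is.finite(ages)))
    stop("branching times must be finite and positive")
  structure(list(ages = ages, n_tips = as.integer(n_tips)),
            class = "branching_times")
}

#' @export
print.branching_times <- function(x, ...) {
  cat(sprintf("Branching times: %d tips, crown age %.4g Myr\n",
              x$n_tips, x$ages[1L]))
  invisible(x)
}

#' Number of reconstructed lineages at a given age
#'
#' Counts 2 crown lineages plus all branching events strictly younger than
#' the crown and strictly older than `age`.  An event at exactly `age` is
#' counted as not yet having occurred (half-open interval `(age, crown]`),
#' so at `age = 0` the count equals the number of tips and at the crown age
#' it equals 2.
#'
#' @param bt a `branching_times` object.
#' @param age age in Myr before present, within `[0, crown_age]`.
#' @return integer lineage count.
#' @export
lineage_count_at <- function(bt, age) {
  bt <- branching_times(bt)
  crown <- bt$ages[1L]
  if (age < 0 || age > crown)
    stop("age must lie in [0, crown_age]")
  2L + sum(bt$ages[-1L] > age)
}

#' Truncation age for gridded pulled-rate estimation
#'
#' Oldest age retained when restricting pulled-rate estimation to time
#' periods in which the reconstructed tree has more than `min_lineages`
#' lineages (periods near the root, where estimation uncertainty is high,
#' are discarded).  The returned age is the branching event that creates the
#' `(min_lineages + 1)`-th lineage; on the open interval just younger than
#' it the lineage count exceeds `min_lineages`.  If the tree never exceeds
#' `min_lineages` lineages the age is 0 and the clade is flagged as
#' un-analyzable for gridded estimation.
#'
#' @param bt a `branching_times` object.
#' @param min_lineages minimum lineage count (default 10, i.e. ">10 species").
#' @return a list with `age` (Myr) and `analyzable` (logical).
#' @export
truncation_age <- function(bt, min_lineages = 10L) {
  bt <- branching_times(bt)
  if (min_lineages < 2L) stop("min_lineages must be >= 2")
  if (bt$n_tips <= min_lineages)
    return(list(age = 0, analyzable = FALSE))
  list(age = bt$ages[min_lineages], analyzable = TRUE)
}

#' Extract maximal clades enriched in a focal region
#'
#' Finds the most inclusive, mutually non-nested clades in which the
#' fraction of tips flagged as inside the focal region (e.g. the Neotropics)
#' is at least `threshold`.  The search starts at the root; a clade that
#' meets the threshold and the size floor is returned whole and not
#' descended into, so no returned clade is nested in another.
#'
#' @param tree a validated tree.
#' @param tip_flags named character/logical vector over all tips; values
#'   `"in"`/`TRUE` mark tips inside the region.
#' @param threshold minimum fraction of in-region tips (default 0.8).
#' @param min_tips minimum clade size (default 2; size-based filtering of the
#'   clade battery is a separate, explicit step).
#' @return a list of `clade_tree` subtrees (possibly empty).
#' @export
extract_neotropical_clades <- function(tree, tip_flags, threshold = 0.8,
                                       min_tips = 2L) {
  if (!inherits(tree, "clade_tree")) tree <- parse_newick(tree)
  if (length(tip_flags) == 0L) stop("empty tip flag map")
  if (is.character(tip_flags)) tip_flags <- tip_flags == "in"
  if (is.null(names(tip_flags)))
    stop("tip_flags must be named by tip label")
  miss <- setdiff(tree$tip.label, names(tip_flags))
  if (length(miss) > 0L)
    stop("unflagged tips: ", paste(utils::head(miss, 3L), collapse = ", "))
  ntip <- ape::Ntip(tree)
  flag <- as.logical(tip_flags[tree$tip.label])

  ## per-node tallies of in-region and total tips (postorder accumulation)
  n_node <- ntip + tree$Nnode
  n_in <- n_tot <- numeric(n_node)
  n_in[seq_len(ntip)] <- as.numeric(flag)
  n_tot[seq_len(ntip)] <- 1
  ord <- rev(order(tree$edge[, 1L]))  # children before parents
  for (i in ord) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    n_in[p] <- n_in[p] + n_in[c]
    n_tot[p] <- n_tot[p] + n_tot[c]
  }

  out <- list()
  visit <- (ntip + 1L)  # root
  while (length(visit) > 0L) {
    node <- visit[1L]; visit <- visit[-1L]
    if (n_tot[node] >= min_tips &&
        n_in[node] / n_tot[node] >= threshold) {
      sub <- if (node == ntip + 1L) tree else ape::extract.clade(tree, node)
      class(sub) <- c("clade_tree", "phylo")
      out[[length(out) + 1L]] <- sub
    } else {
      kids <- tree$edge[tree$edge[, 1L] == node, 2L]
      visit <- c(visit, kids[kids > ntip])
      ## qualifying single tips are ignored unless min_tips == 1
      if (min_tips <= 1L) {
        for (k in kids[kids <= ntip]) {
          if (flag[k]) out[[length(out) + 1L]] <- tree$tip.label[k]
        }
      }
    }
  }
  out
}
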