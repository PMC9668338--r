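#' The 13 operational Neotropical regions
#'
#' Fixed column vocabulary for clade-by-region abundance matrices.
#' @export
neotropical_regions <- function() {
  c("Amazonia", "Atlantic_Forest", "Bahama_Antilles", "Caatinga",
    "Central_Andes", "Cerrado", "Chaco", "Choco", "Guiana_Shield",
    "Mesoamerica", "Northern_Andes", "temperate_South_America", "elsewhere")
}

#' Validate a clade-by-region abundance matrix
#'
#' @param m matrix or data frame: rows are clades, columns regions, entries
#'   non-negative species counts.
#' @param regions expected column vocabulary; `NULL` skips the name check.
#' @return a numeric matrix with rownames.
#' @export
abundance_matrix <- function(m, regions = NULL) {
  m <- as.matrix(m)
  if (!is.numeric(m) || any(m < 0) || anyNA(m))
    stop("abundance matrix must be non-negative numeric with no NAs")
  if (!is.null(regions) && !identical(colnames(m), regions))
    stop("column names must match the fixed region vocabulary")
  if (is.null(rownames(m))) rownames(m) <- paste0("clade_", seq_len(nrow(m)))
  m
}

#' Hellinger transformation of clade rows
#'
#' y_ij = sqrt(x_ij / sum_j x_ij): square root of the row-relative
#' abundances, so each row's squared values sum to 1.  Down-weights
#' species-rich clades before distances are computed.  All-zero clade rows
#' are dropped with a warning.
#'
#' @param m an abundance matrix (clades x regions).
#' @return the transformed matrix.
#' @export
hellinger_rows <- function(m) {
  m <- abundance_matrix(m)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero clade row(s) dropped")
    m <- m[!zero, , drop = FALSE]
  }
  vegan::decostand(m, method = "hellinger")
}

#' Morisita-Horn dissimilarity between region columns
#'
#' d(a, b) = 1 - 2 sum(a_i b_i) / ((sum a_i^2/A^2 + sum b_i^2/B^2) A B),
#' with A, B the column totals: an abundance-based assemblage distance in
#' `[0, 1]`, insensitive to total-abundance scaling.  Columns with no
#' positive entries are excluded with a warning (their distances are
#' undefined).
#'
#' @param m a (possibly Hellinger-transformed) clades-by-regions matrix.
#' @return a `dist` object over the (retained) regions.
#' @export
morisita_horn <- function(m) {
  m <- as.matrix(m)
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning("all-zero region column(s) excluded: ",
            paste(colnames(m)[empty], collapse = ", "))
    m <- m[, !empty, drop = FALSE]
  }
  vegan::vegdist(t(m), method = "horn")
}

#' Embed a dissimilarity and cluster regions with K-means
#'
#' Classical (metric) multidimensional scaling of the dissimilarity,
#' retaining positive-eigenvalue coordinates covering at least 95% of the
#' positive variance, followed by K-means with `n_init` restarts under a
#' fixed seed.
#'
#' @param d a `dist` over regions (e.g. [morisita_horn()]).
#' @param k number of clusters.
#' @param n_init K-means restarts (default 100).
#' @param seed RNG seed.
#' @return an object of class `region_clustering`: list with `k`,
#'   `assignment` (named integer vector), `wss` (total within-cluster sum
#'   of squares at this k), `coords`, `seed`, `n_init`.
#' @export
embed_and_cluster <- function(d, k, n_init = 100L, seed = 1L) {
  n <- attr(d, "Size")
  if (k > n) stop("k cannot exceed the number of regions")
  coords <- mds_coords(d)
  if (k == n) {
    ## degenerate: every region its own cluster, WSS = 0
    assignment <- stats::setNames(seq_len(n), rownames(coords))
    return(structure(list(k = k, assignment = assignment, wss = 0,
                          coords = coords, seed = seed, n_init = n_init),
                     class = "region_clustering"))
  }
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k, nstart = n_init, iter.max = 100L)
  structure(list(k = k, assignment = stats::setNames(km$cluster,
                                                     rownames(coords)),
                 wss = km$tot.withinss, coords = coords,
                 seed = seed, n_init = n_init),
            class = "region_clustering")
}

## MDS coordinates keeping positive eigenvalues up to 95% of positive variance
mds_coords <- function(d) {
  n <- attr(d, "Size")
  mds <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- mds$eig
  n_pos <- sum(eig > 1e-10)
  if (n_pos == 0L) stop("dissimilarity has no positive MDS eigenvalues")
  cum <- cumsum(eig[seq_len(n_pos)]) / sum(eig[seq_len(n_pos)])
  j <- which(cum >= 0.95 - 1e-12)[1L]
  coords <- mds$points[, seq_len(min(j, ncol(mds$points))), drop = FALSE]
  rownames(coords) <- attr(d, "Labels")
  coords
}

#' Within-cluster sum of squares across candidate k
#'
#' @param d dissimilarity over regions.
#' @param k_max largest k to evaluate (default: number of regions).
#' @inheritParams embed_and_cluster
#' @return named numeric vector `wss[k]` for k = 1..k_max (non-increasing).
#' @export
wss_curve <- function(d, k_max = attr(d, "Size"), n_init = 100L, seed = 1L) {
  coords <- mds_coords(d)
  vapply(seq_len(k_max), function(k) {
    set.seed(seed + k)
    stats::kmeans(coords, centers = k, nstart = n_init,
                  iter.max = 100L)$tot.withinss
  }, 0) -> wss
  stats::setNames(cummin(wss), seq_len(k_max))
}

#' Choose k by the elbow method
#'
#' Picks the interior k maximizing the second difference
#' `WSS(k-1) - 2 WSS(k) + WSS(k+1)` (the sharpest kink in the curve); ties
#' go to the smallest k.
#'
#' @param wss_by_k named vector of WSS values for k = 1..k_max (>= 3 values).
#' @return the chosen k (integer).
#' @export
elbow_choose_k <- function(wss_by_k) {
  w <- as.numeric(wss_by_k)
  if (length(w) < 3L) stop("need WSS for at least 3 candidate k")
  curv <- w[-c(length(w) - 1L, length(w))] - 2 * w[-c(1L, length(w))] +
    w[-c(1L, 2L)]
  as.integer(which.max(curv) + 1L)
}

#' Assign clades to region clusters
#'
#' A clade is assigned to the cluster holding the largest share of its
#' species counts only if that share strictly exceeds `threshold` (">60%
#' of the species"); otherwise it is `"mixed"`.  Ties in the largest share
#' are conservative: `"mixed"`.  Clades with zero total count are excluded
#' with a warning.
#'
#' @param m an abundance matrix (raw counts).
#' @param clustering a [embed_and_cluster()] result covering the columns
#'   of `m`.
#' @param threshold assignment share (default 0.6, strict).
#' @return an object of class `clade_assignment`: data.frame with
#'   `clade_id`, `cluster` (integer or NA for mixed), `label`
#'   ("cluster_k" or "mixed"), `fraction` (share in the argmax cluster).
#' @export
assign_clades <- function(m, clustering, threshold = 0.6) {
  m <- abundance_matrix(m)
  asg <- clustering$assignment
  miss <- setdiff(colnames(m), names(asg))
  if (length(miss) > 0L)
    stop("clustering does not cover region(s): ", paste(miss, collapse = ", "))
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning(sum(zero), " zero-count clade(s) excluded")
    m <- m[!zero, , drop = FALSE]
  }
  shares <- t(apply(m, 1L, function(x) {
    tapply(x, asg[colnames(m)], sum) / sum(x)
  }))
  res <- data.frame(clade_id = rownames(m), cluster = NA_integer_,
                    label = "mixed", fraction = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(shares))) {
    top <- max(shares[i, ])
    res$fraction[i] <- top
    tied <- sum(shares[i, ] == top) > 1L
    if (!tied && top > threshold) {
      cl <- as.integer(colnames(shares)[which.max(shares[i, ])])
      res$cluster[i] <- cl
      res$label[i] <- paste0("cluster_", cl)
    }
  }
  class(res) <- c("clade_assignment", "data.frame")
  res
}

#' @export
print.region_clustering <- function(x, ...) {
  cat(sprintf("Region clustering: k = %d (seed %d, %d restarts), WSS = %.4g\n",
              x$k, x$seed, x$n_init, x$wss))
  print(split(names(x$assignment), x$assignment))
  invisible(x)
}
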