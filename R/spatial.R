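# Spatial statistics of the immune infiltrate.
#
# The radial distribution (pair-correlation) function g(r) compares the
# observed pair-distance histogram of immune cell positions with the
# expectation under complete spatial randomness (CSR) on the same admissible
# node set; edge effects are handled exactly by computing the CSR expectation
# from the admissible-node pair-distance census rather than by a boundary
# approximation. g(r) ~ 1 under CSR; g >> 1 at small r indicates clustering.
# A power law g(r) ~ b * r^-m is fitted by ordinary least squares on
# log-log scale: m is the decay slope, b the amplitude at r = 1 node
# (a proxy for the probability of finding a neighbor immune cell).

# pairwise Euclidean distance histogram of all admissible node pairs,
# cached on the domain
pair_census <- function(domain, r_max, bin_width) {
  key <- paste0("census_", r_max, "_", bin_width)
  if (!is.null(domain$cache[[key]])) return(domain$cache[[key]])
  adm <- admissible_nodes(domain)
  xy <- idx_to_xy(adm, domain$width)
  n_bins <- as.integer(ceiling(r_max / bin_width))
  counts <- numeric(n_bins)
  chunk <- 512L
  n <- nrow(xy)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d <- sqrt(outer(xy[s:e, 1], xy[, 1], "-")^2 +
                outer(xy[s:e, 2], xy[, 2], "-")^2)
    # count each unordered pair once: keep j > i
    jj <- matrix(rep(seq_len(n), each = e - s + 1L), nrow = e - s + 1L)
    d <- d[jj > (s:e)]
    d <- d[d < r_max]
    b <- pmin(floor(d / bin_width) + 1L, n_bins)
    counts <- counts + tabulate(b, n_bins)
  }
  res <- list(counts = counts, n_nodes = n,
              r_centers = (seq_len(n_bins) - 0.5) * bin_width)
  domain$cache[[key]] <- res
  res
}

points_to_idx <- function(points, domain) {
  if (is.matrix(points) || is.data.frame(points)) {
    xy_to_idx(as.integer(points[, 1]), as.integer(points[, 2]), domain$width)
  } else {
    as.integer(points)
  }
}

#' Radial distribution function of a lattice point pattern
#'
#' @param points immune cell positions: linear node indices, or a two-column
#'   matrix/data frame of (x, y) node coordinates (>= 2 points).
#' @param domain a [tdlu_domain].
#' @param r_max maximum distance, nodes; default half the domain diameter.
#' @param bin_width annulus width, nodes (default 1).
#' @return data frame with `r` (bin centers) and `g`.
#' @export
radial_distribution <- function(points, domain, r_max = NULL, bin_width = 1) {
  idx <- points_to_idx(points, domain)
  if (length(idx) < 2) stop("radial_distribution needs at least 2 points")
  if (any(domain$comp_v[idx] == COMPARTMENTS[["LUMEN"]]) || any(idx > domain$width * domain$height)) {
    stop("points must lie on admissible (non-lumen) domain nodes")
  }
  if (is.null(r_max)) {
    r_max <- sqrt(domain$width^2 + domain$height^2) / 2
  }
  cen <- pair_census(domain, r_max, bin_width)
  n_bins <- length(cen$counts)
  xy <- idx_to_xy(idx, domain$width)
  d <- stats::dist(xy)
  d <- d[d < r_max]
  b <- pmin(floor(d / bin_width) + 1L, n_bins)
  obs <- tabulate(b, n_bins)
  n <- length(idx)
  N <- cen$n_nodes
  # probability that both nodes of an admissible pair are occupied under a
  # uniform draw of n occupied nodes without replacement
  expected <- cen$counts * n * (n - 1) / (N * (N - 1))
  g <- ifelse(expected > 0, obs / expected, NA_real_)
  data.frame(r = cen$r_centers, g = g)
}

#' Fit a power law g(r) ~ b * r^-m
#'
#' Ordinary least squares of `log(g)` on `log(r)` over bins with `g > 0`.
#'
#' @param r_centers bin centers (nodes).
#' @param g_values pair-correlation estimates.
#' @return An `rdf_fit` list: `r_centers`, `g_values`, `b`, `m`, `r2`,
#'   and `g_first` (the estimate in the first positive bin).
#' @export
fit_power_law <- function(r_centers, g_values) {
  if (is.data.frame(r_centers)) {
    g_values <- r_centers$g
    r_centers <- r_centers$r
  }
  ok <- !is.na(g_values) & g_values > 0 & r_centers > 0
  if (!any(ok)) stop("fit_power_law: all g values are zero or undefined")
  if (sum(ok) < 3) stop("fit_power_law needs at least 3 positive bins")
  lx <- log(r_centers[ok])
  ly <- log(g_values[ok])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  structure(list(
    r_centers = r_centers, g_values = g_values,
    b = exp(fit$coefficients[[1]]), m = -fit$coefficients[[2]],
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    g_first = g_values[which(ok)[1]]
  ), class = "rdf_fit")
}

#' @export
print.rdf_fit <- function(x, ...) {
  cat(sprintf("Power-law fit g(r) ~ b * r^-m: b = %.4g, m = %.4g (R2 = %.3f)\n",
              x$b, x$m, x$r2))
  invisible(x)
}

#' Immune cell counts by distance to the epithelium
#'
#' Bands: 0 (in contact with / on the epithelium), 1, 2 and >= 3 nodes away,
#' from the domain's breadth-first distance map. Counts are normalized by the
#' epithelial cell count.
#'
#' @param immune_points positions (indices or (x, y) matrix).
#' @param domain a [tdlu_domain].
#' @param n_epithelial normalizing epithelial count (defaults to the domain's
#'   epithelial node count).
#' @return data frame with `band` (`"0"`, `"1"`, `"2"`, `">=3"`), `count`,
#'   `relative`.
#' @export
contact_profile <- function(immune_points, domain,
                            n_epithelial = domain$n_epithelial) {
  idx <- points_to_idx(immune_points, domain)
  d <- as.integer(domain$dist_epi)[idx]
  band <- cut(pmin(d, 3L), breaks = c(-1, 0, 1, 2, 3),
              labels = c("0", "1", "2", ">=3"))
  counts <- as.integer(table(factor(band, levels = c("0", "1", "2", ">=3"))))
  data.frame(band = c("0", "1", "2", ">=3"), count = counts,
             relative = counts / n_epithelial)
}

#' Cluster statistics of an immune point pattern
#'
#' Connected components of the occupied nodes under Moore (8-)adjacency; a
#' cluster is a component with at least `cluster_min` cells.
#'
#' @param immune_points positions (indices or (x, y) matrix).
#' @param domain a [tdlu_domain] (used for coordinate conversion).
#' @param cluster_min minimum component size counted as a cluster (default 3).
#' @return list `(n_clusters, sizes, membership)`; `sizes` are the sizes of
#'   all components of size >= `cluster_min` (decreasing), `membership` maps
#'   each point to its component.
#' @export
cluster_stats <- function(immune_points, domain, cluster_min = 3) {
  idx <- points_to_idx(immune_points, domain)
  n <- length(idx)
  if (n == 0) {
    return(list(n_clusters = 0L, sizes = integer(), membership = integer()))
  }
  xy <- idx_to_xy(idx, domain$width)
  # Moore adjacency: Chebyshev distance 1
  pairs <- which(
    outer(xy[, 1], xy[, 1], function(a, b) abs(a - b)) <= 1 &
      outer(xy[, 2], xy[, 2], function(a, b) abs(a - b)) <= 1,
    arr.ind = TRUE
  )
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(pairs)) gr <- igraph::add_edges(gr, t(pairs))
  comp <- igraph::components(gr)
  sizes <- sort(comp$csize[comp$csize >= cluster_min], decreasing = TRUE)
  list(n_clusters = length(sizes), sizes = as.integer(sizes),
       membership = comp$membership[seq_len(n)])
}

#' Export an RDF fit as CSV (`r,g,b_fit,m_fit,r2`)
#' @param fit an `rdf_fit`.
#' @param path output path.
#' @export
write_rdf_csv <- function(fit, path) {
  utils::write.csv(
    data.frame(r = fit$r_centers, g = fit$g_values,
               b_fit = fit$b, m_fit = fit$m, r2 = fit$r2),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Export cluster statistics as JSON
#' @param cs result of [cluster_stats()].
#' @param path output path.
#' @export
write_cluster_json <- function(cs, path) {
  jsonlite::write_json(
    list(n_clusters = cs$n_clusters, sizes = cs$sizes,
         size_histogram = as.list(table(cs$sizes))),
    path, auto_unbox = TRUE
  )
  invisible(path)
}
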