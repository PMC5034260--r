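# Packaged fixtures: calibration targets and synthetic point patterns.
#
# All fixtures are pure functions of their arguments and seed; the CSV files
# under inst/extdata are generated by these functions and kept under version
# control so every input of the analysis is explicit and swappable.

#' Calibration target fixture
#'
#' Per-phase mean relative immune cell numbers with tolerances: effector
#' means 0.05 +/- 0.01 (follicular, day 1-11), 0.04 +/- 0.01 (in-between,
#' day 11-17), 0.07 +/- 0.02 (luteal, day 17-28) and the overall regulatory
#' mean 0.055 +/- 0.01.
#'
#' @return data frame with columns `phase`, `target_mean`, `tolerance`.
#' @export
make_calibration_fixture <- function() {
  data.frame(
    phase = c("follicular", "inbetween", "luteal", "regulatory_all"),
    target_mean = c(0.05, 0.04, 0.07, 0.055),
    tolerance = c(0.01, 0.01, 0.02, 0.01),
    stringsAsFactors = FALSE
  )
}

#' Write a calibration fixture as CSV (`phase,target_mean,tolerance`)
#' @param fixture data frame from [make_calibration_fixture()].
#' @param path output path.
#' @export
write_calibration_csv <- function(fixture, path) {
  utils::write.csv(fixture, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration fixture CSV
#' @param path CSV with columns `phase,target_mean,tolerance`.
#' @return data frame.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase", "target_mean", "tolerance")
  if (!all(need %in% names(df))) {
    stop("calibration CSV must have columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(df$target_mean >= 0), all(df$tolerance > 0))
  df
}

#' Path of a packaged fixture file
#' @param name file name under `inst/extdata`.
#' @return absolute path.
#' @export
fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "tdlusim")
  if (p == "") stop("packaged fixture not found: ", name)
  p
}

#' Generate a synthetic point pattern with known structure
#'
#' Supports `csr` (uniform on the admissible node set), `clustered`
#' (parent/offspring: `n_parents` parents with Gaussian offspring scatter
#' `sigma`) and `power_law` (offspring displaced from parents with radial
#' density ~ r^-`alpha` between 1 and `r_max` nodes, producing an
#' approximately power-law pair correlation at short range).
#'
#' @param kind `"csr"`, `"clustered"` or `"power_law"`.
#' @param n number of points (>= 2).
#' @param domain a [tdlu_domain].
#' @param params list of kind-specific parameters (`n_parents`, `sigma`,
#'   `alpha`, `r_max`).
#' @param seed integer seed.
#' @return integer vector of distinct admissible linear node indices, with
#'   attribute `truth` describing the construction.
#' @export
make_synthetic_pattern <- function(kind = c("csr", "clustered", "power_law"),
                                   n, domain, params = list(), seed = 1) {
  kind <- match.arg(kind)
  if (n < 2) stop("make_synthetic_pattern needs n >= 2")
  adm <- admissible_nodes(domain)
  if (n > length(adm)) stop("n exceeds the number of admissible nodes")
  with_seed(seed, {
    if (kind == "csr") {
      pts <- sample(adm, n)
      truth <- list(kind = "csr")
    } else {
      n_parents <- params$n_parents %||% 5L
      sigma <- params$sigma %||% 1.5
      alpha <- params$alpha %||% 2
      r_lim <- params$r_max %||% 15
      parents_idx <- sample(adm, n_parents)
      pxy <- idx_to_xy(parents_idx, domain$width)
      taken <- logical(domain$width * domain$height + 1L)
      pts <- integer(0)
      adm_set <- logical(domain$width * domain$height)
      adm_set[adm] <- TRUE
      guard <- 0L
      while (length(pts) < n && guard < 200L * n) {
        guard <- guard + 1L
        p <- sample.int(n_parents, 1L)
        if (kind == "clustered") {
          off <- round(stats::rnorm(2, 0, sigma))
        } else {
          # radius with density ~ r^-alpha on [1, r_lim] (inverse transform)
          u <- stats::runif(1)
          r <- if (alpha == 1) exp(u * log(r_lim)) else {
            ((1 - u) + u * r_lim^(1 - alpha))^(1 / (1 - alpha))
          }
          ang <- stats::runif(1, 0, 2 * pi)
          off <- round(r * c(cos(ang), sin(ang)))
        }
        x <- pxy[p, 1] + off[1]
        y <- pxy[p, 2] + off[2]
        if (x < 1 || x > domain$width || y < 1 || y > domain$height) next
        idx <- xy_to_idx(x, y, domain$width)
        if (!adm_set[idx] || taken[idx]) next
        taken[idx] <- TRUE
        pts <- c(pts, idx)
      }
      if (length(pts) < n) {
        extra <- setdiff(adm, pts)
        pts <- c(pts, sample(extra, n - length(pts)))
      }
      truth <- list(kind = kind, n_parents = n_parents, sigma = sigma,
                    alpha = alpha, parents = parents_idx)
    }
    structure(as.integer(pts), truth = truth)
  })
}
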