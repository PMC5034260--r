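# Lattice geometry of a simulated TDLU cross-section.
#
# The domain is a square lattice. Each node carries one compartment label:
# LUMEN, LUMINAL_EPITHELIUM, MYOEPITHELIUM, INTRALOBULAR_STROMA or
# INTERLOBULAR_STROMA. Node spacing is nominally one cell diameter (~10 um);
# one node holds at most one cell. Cell-cell contact and immune movement use
# the Moore (8-)neighborhood; the diffusion stencil uses the von Neumann
# (4-)neighborhood.

#' Compartment codes of the TDLU lattice
#'
#' Integer codes used in the `compartment` matrix of a [tdlu_domain].
#' @format Named integer vector of length 5.
#' @export
COMPARTMENTS <- c(
  LUMEN = 1L,
  LUMINAL_EPITHELIUM = 2L,
  MYOEPITHELIUM = 3L,
  INTRALOBULAR_STROMA = 4L,
  INTERLOBULAR_STROMA = 5L
)

comp_label <- function(code) names(COMPARTMENTS)[code]

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded helpers do not
#' perturb the caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# linear index <-> coordinates (matrix is width x height, column-major)
xy_to_idx <- function(x, y, width) x + (y - 1L) * width
idx_to_xy <- function(idx, width) {
  x <- ((idx - 1L) %% width) + 1L
  y <- ((idx - 1L) %/% width) + 1L
  cbind(x = x, y = y)
}

# Neighbor lookup table: (width*height + 1) x k integer matrix of linear
# indices; off-grid neighbors and the dummy row map to the sentinel index
# width*height + 1.
neighbor_table <- function(width, height, moore = TRUE) {
  n <- width * height
  sentinel <- n + 1L
  x <- rep.int(seq_len(width), height)
  y <- rep(seq_len(height), each = width)
  if (moore) {
    dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  } else {
    dx <- c(0L, -1L, 1L, 0L)
    dy <- c(-1L, 0L, 0L, 1L)
  }
  nb <- matrix(sentinel, nrow = n + 1L, ncol = length(dx))
  for (k in seq_along(dx)) {
    nx <- x + dx[k]
    ny <- y + dy[k]
    ok <- nx >= 1L & nx <= width & ny >= 1L & ny <= height
    nb[seq_len(n)[ok], k] <- xy_to_idx(nx[ok], ny[ok], width)
  }
  nb
}

# 4-neighborhood dilation of a node set given as linear indices
dilate4 <- function(idx, nb_vn, n) {
  out <- unique(as.vector(nb_vn[idx, , drop = FALSE]))
  out[out <= n]
}

# one acinus: lumen disc of Euclidean radius r around (cx, cy), then two
# concentric one-node rings obtained by successive 4-neighborhood dilation
acinus_nodes <- function(cx, cy, lumen_radius, width, height, nb_vn) {
  n <- width * height
  rx <- seq.int(max(1L, cx - lumen_radius), min(width, cx + lumen_radius))
  ry <- seq.int(max(1L, cy - lumen_radius), min(height, cy + lumen_radius))
  g <- expand.grid(x = rx, y = ry)
  d2 <- (g$x - cx)^2 + (g$y - cy)^2
  lumen <- xy_to_idx(g$x[d2 <= lumen_radius^2], g$y[d2 <= lumen_radius^2], width)
  luminal <- setdiff(dilate4(lumen, nb_vn, n), lumen)
  myo <- setdiff(dilate4(c(lumen, luminal), nb_vn, n), c(lumen, luminal))
  list(lumen = lumen, luminal = luminal, myo = myo)
}

# candidate acinus centers: middle of the grid, then concentric rings of
# 6*k points at radius k*spacing (hexagonal-style packing)
ring_positions <- function(n_acini, spacing, width, height) {
  cx <- (width + 1) / 2
  cy <- (height + 1) / 2
  pos <- matrix(c(round(cx), round(cy)), ncol = 2)
  k <- 1L
  while (nrow(pos) < n_acini) {
    ang <- 2 * pi * (seq_len(6L * k) - 1L) / (6L * k) + (k %% 2) * pi / (6L * k)
    pos <- rbind(pos, cbind(
      round(cx + k * spacing * cos(ang)),
      round(cy + k * spacing * sin(ang))
    ))
    k <- k + 1L
  }
  pos[seq_len(n_acini), , drop = FALSE]
}

#' Build a simulated TDLU cross-section lattice
#'
#' Places `n_acini` acini (lumen disc + one-node luminal ring + one-node
#' myoepithelial ring) on a jittered hexagonal-style arrangement inside a
#' square lattice. The TDLU polygon separating intra- from interlobular stroma
#' is the convex hull of the epithelial nodes dilated outward by
#' `stromal_margin` nodes, a parametric stand-in for the pathologist-annotated
#' boundary.
#'
#' @param n_acini number of acini (>= 1).
#' @param lumen_radius Euclidean radius of each lumen disc, in nodes.
#' @param acinus_spacing spacing between acinus centers, in nodes.
#' @param grid_size lattice side length, in nodes.
#' @param seed integer seed controlling the placement jitter.
#' @param stromal_margin outward dilation of the TDLU polygon, in nodes.
#' @param jitter maximum per-axis placement jitter, in nodes.
#' @param epi_band permissible range for the total epithelial node count
#'   (the quantification band of the underlying histology is 250 to 2500
#'   epithelial cells per lobular structure); `NULL` disables the check.
#' @return A `tdlu_domain` object: list with `width`, `height`, `compartment`
#'   (integer matrix of [COMPARTMENTS] codes), `comp_v` (linear vector with a
#'   sentinel LUMEN entry), `tdlu_polygon`, `dist_epi`, neighbor tables
#'   `nb_moore`/`nb_vn`, acinus centers and `n_epithelial`.
#' @export
build_tdlu <- function(n_acini = 18L, lumen_radius = 2L, acinus_spacing = 11L,
                       grid_size = 60L, seed = 1L, stromal_margin = 3L,
                       jitter = 1L, epi_band = c(250L, 2500L)) {
  if (n_acini < 1) stop("geometry-infeasible: n_acini must be >= 1")
  if (lumen_radius < 1) stop("geometry-infeasible: lumen_radius must be >= 1")
  width <- height <- as.integer(grid_size)
  n <- width * height
  nb_vn <- neighbor_table(width, height, moore = FALSE)
  nb_moore <- neighbor_table(width, height, moore = TRUE)

  base_pos <- ring_positions(n_acini, acinus_spacing, width, height)
  # two acini (max node extent lumen_radius + 2 from the center) have
  # disjoint node sets when their centers are further apart than twice that
  # extent; actual overlap is re-checked when carving
  min_sep <- 2 * (lumen_radius + 2) + 0.5

  centers <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_acini, ncol = 2)
    for (i in seq_len(n_acini)) {
      placed <- FALSE
      margin <- lumen_radius + 2
      feasible <- function(cand) {
        ok_sep <- i == 1L ||
          all(sqrt(rowSums((out[seq_len(i - 1L), , drop = FALSE] -
                              matrix(cand, i - 1L, 2, byrow = TRUE))^2)) >= min_sep)
        ok_sep && all(cand - margin >= 1) && all(cand + margin <= grid_size)
      }
      for (try in seq_len(30L)) {
        cand <- base_pos[i, ] + sample(seq.int(-jitter, jitter), 2, replace = TRUE)
        if (feasible(cand)) {
          out[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed && feasible(base_pos[i, ])) {
        # fall back to the unjittered grid position
        out[i, ] <- base_pos[i, ]
        placed <- TRUE
      }
      if (!placed) {
        stop("geometry-infeasible: cannot place acinus ", i,
             " without ring overlap or grid-boundary crossing ",
             "(increase grid_size or acinus_spacing)")
      }
    }
    out
  })

  compartment <- matrix(0L, nrow = width, ncol = height)
  for (i in seq_len(n_acini)) {
    ac <- acinus_nodes(centers[i, 1], centers[i, 2], lumen_radius,
                       width, height, nb_vn)
    all_nodes <- c(ac$lumen, ac$luminal, ac$myo)
    if (any(compartment[all_nodes] != 0L)) {
      stop("geometry-infeasible: acinus ", i, " overlaps a previously placed acinus")
    }
    compartment[ac$lumen] <- COMPARTMENTS[["LUMEN"]]
    compartment[ac$luminal] <- COMPARTMENTS[["LUMINAL_EPITHELIUM"]]
    compartment[ac$myo] <- COMPARTMENTS[["MYOEPITHELIUM"]]
  }

  epi_idx <- which(compartment == COMPARTMENTS[["LUMINAL_EPITHELIUM"]] |
                     compartment == COMPARTMENTS[["MYOEPITHELIUM"]])
  n_epithelial <- length(epi_idx)
  if (!is.null(epi_band) &&
      (n_epithelial < epi_band[1] || n_epithelial > epi_band[2])) {
    stop("geometry-infeasible: epithelial node count ", n_epithelial,
         " outside the configured band [", epi_band[1], ", ", epi_band[2], "]")
  }

  # TDLU polygon: dilated convex hull of the epithelial node coordinates
  epi_xy <- idx_to_xy(epi_idx, width)
  hull <- grDevices::chull(epi_xy)
  hv <- epi_xy[hull, , drop = FALSE]
  ctr <- colMeans(epi_xy)
  dir <- sweep(hv, 2, ctr)
  len <- sqrt(rowSums(dir^2))
  poly <- hv + dir / len * stromal_margin
  colnames(poly) <- c("x", "y")

  unassigned <- which(compartment == 0L)
  un_xy <- idx_to_xy(unassigned, width)
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(un_xy[, 1], un_xy[, 2]))
  compartment[unassigned[inside]] <- COMPARTMENTS[["INTRALOBULAR_STROMA"]]
  compartment[unassigned[!inside]] <- COMPARTMENTS[["INTERLOBULAR_STROMA"]]

  comp_v <- c(as.integer(compartment), COMPARTMENTS[["LUMEN"]])

  dom <- structure(list(
    width = width, height = height,
    compartment = compartment, comp_v = comp_v,
    tdlu_polygon = poly,
    nb_moore = nb_moore, nb_vn = nb_vn,
    acini = data.frame(x = centers[, 1], y = centers[, 2]),
    n_epithelial = n_epithelial,
    cache = new.env(parent = emptyenv())
  ), class = "tdlu_domain")
  dom$dist_epi <- distance_to_epithelium(dom)
  dom
}

#' @export
print.tdlu_domain <- function(x, ...) {
  cat("TDLU lattice domain ", x$width, "x", x$height, " nodes\n", sep = "")
  cat("  acini: ", nrow(x$acini), ", epithelial nodes: ", x$n_epithelial, "\n", sep = "")
  tab <- table(factor(comp_label(as.integer(x$compartment)),
                      levels = names(COMPARTMENTS)))
  for (nm in names(tab)) cat(sprintf("  %-22s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Lattice distance to the nearest epithelial node
#'
#' Breadth-first (Moore neighborhood) distance from the set of epithelial
#' nodes over all non-lumen nodes. Epithelial nodes have distance 0; lumen
#' nodes are excluded (NA).
#'
#' @param domain a [tdlu_domain].
#' @return integer matrix (width x height); NA on LUMEN nodes.
#' @export
distance_to_epithelium <- function(domain) {
  n <- domain$width * domain$height
  comp <- as.integer(domain$compartment)
  dist <- rep(NA_integer_, n)
  blocked <- comp == COMPARTMENTS[["LUMEN"]]
  frontier <- which(comp == COMPARTMENTS[["LUMINAL_EPITHELIUM"]] |
                      comp == COMPARTMENTS[["MYOEPITHELIUM"]])
  dist[frontier] <- 0L
  d <- 0L
  while (length(frontier)) {
    nxt <- unique(as.vector(domain$nb_moore[frontier, , drop = FALSE]))
    nxt <- nxt[nxt <= n]
    nxt <- nxt[is.na(dist[nxt]) & !blocked[nxt]]
    d <- d + 1L
    dist[nxt] <- d
    frontier <- nxt
  }
  matrix(dist, nrow = domain$width)
}

#' Nodes admissible for immune cells (all non-lumen nodes)
#' @param domain a [tdlu_domain].
#' @return integer vector of linear node indices.
#' @export
admissible_nodes <- function(domain) {
  which(as.integer(domain$compartment) != COMPARTMENTS[["LUMEN"]])
}

#' Stromal nodes (intra- plus interlobular)
#' @param domain a [tdlu_domain].
#' @return integer vector of linear node indices.
#' @export
stromal_nodes <- function(domain) {
  comp <- as.integer(domain$compartment)
  which(comp == COMPARTMENTS[["INTRALOBULAR_STROMA"]] |
          comp == COMPARTMENTS[["INTERLOBULAR_STROMA"]])
}

#' Moore or von Neumann neighbors of a node
#' @param domain a [tdlu_domain].
#' @param node linear node index.
#' @param type `"moore"` (contact/movement) or `"vonneumann"` (diffusion).
#' @return integer vector of in-grid neighbor indices.
#' @export
node_neighbors <- function(domain, node, type = c("moore", "vonneumann")) {
  type <- match.arg(type)
  nb <- if (type == "moore") domain$nb_moore[node, ] else domain$nb_vn[node, ]
  nb[nb <= domain$width * domain$height]
}

#' Check all structural invariants of a TDLU domain
#'
#' Verifies: compartments partition all nodes; every luminal-epithelium node
#' touches a myoepithelial node; no lumen node touches stroma; distance map is
#' zero exactly on epithelial nodes.
#'
#' @param domain a [tdlu_domain].
#' @return TRUE invisibly; stops with a message on violation.
#' @export
validate_domain <- function(domain) {
  comp <- as.integer(domain$compartment)
  n <- domain$width * domain$height
  if (any(!comp %in% COMPARTMENTS)) stop("unlabelled nodes present")
  lum_epi <- which(comp == COMPARTMENTS[["LUMINAL_EPITHELIUM"]])
  comp_ext <- c(comp, COMPARTMENTS[["LUMEN"]])
  has_myo <- rowSums(matrix(
    comp_ext[domain$nb_moore[lum_epi, , drop = FALSE]] == COMPARTMENTS[["MYOEPITHELIUM"]],
    nrow = length(lum_epi)
  )) > 0
  if (!all(has_myo)) stop("a LUMINAL_EPITHELIUM node lacks a MYOEPITHELIUM neighbor")
  lum <- which(comp == COMPARTMENTS[["LUMEN"]])
  nb_comp <- matrix(comp_ext[domain$nb_moore[lum, , drop = FALSE]], nrow = length(lum))
  if (any(nb_comp >= COMPARTMENTS[["INTRALOBULAR_STROMA"]])) {
    stop("a LUMEN node is adjacent to stroma")
  }
  d <- as.integer(domain$dist_epi)
  epi <- comp %in% COMPARTMENTS[c("LUMINAL_EPITHELIUM", "MYOEPITHELIUM")]
  if (!all(d[epi] == 0L) || any(d[!epi] == 0L, na.rm = TRUE)) {
    stop("dist_epi is not zero exactly on epithelial nodes")
  }
  invisible(TRUE)
}

#' Export a domain's compartment labels as TSV
#'
#' Columns `node_x`, `node_y`, `compartment` (exact labels of [COMPARTMENTS]).
#' @param domain a [tdlu_domain].
#' @param path output file path.
#' @export
write_domain_tsv <- function(domain, path) {
  idx <- seq_len(domain$width * domain$height)
  xy <- idx_to_xy(idx, domain$width)
  df <- data.frame(node_x = xy[, 1], node_y = xy[, 2],
                   compartment = comp_label(as.integer(domain$compartment)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a compartment TSV back into a label matrix
#' @param path TSV written by [write_domain_tsv()].
#' @return integer compartment matrix.
#' @export
read_domain_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  width <- max(df$node_x)
  height <- max(df$node_y)
  m <- matrix(NA_integer_, width, height)
  m[cbind(df$node_x, df$node_y)] <- COMPARTMENTS[df$compartment]
  m
}
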