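# Chemokine reaction-diffusion fields.
#
# Two continuous nonnegative concentration fields live on the lattice: one
# sourced by damaged epithelial cells (C_dam), one by dying epithelial cells
# (C_dying, the "find-me" signal). Each evolves by explicit forward-Euler
# diffusion (von Neumann 4-point stencil), linear decay and per-source
# secretion, with zero-flux boundaries at grid edges and at lumen boundaries
# (lumina are reflecting obstacles, consistent with immune exclusion from
# lumina). Default parameters (D = 5 nodes^2/h, lambda = 0.5 /h, s = 1
# units/h) give a quasi-steady halo of roughly sqrt(D/lambda) ~ 3 nodes
# e-folding length around a single source, so a lone damaged cell recruits
# immune cells within a ~5-10 node neighborhood rather than globally.

#' Construct chemokine fields on a domain
#'
#' @param domain a [tdlu_domain].
#' @param D_dam,D_dying diffusion coefficients, nodes^2 per hour.
#' @param lambda_dam,lambda_dying decay rates, per hour.
#' @param s_dam,s_dying secretion rates per source cell, units per hour.
#' @return A `chemokine_fields` object (fields start at zero).
#' @export
chemokine_fields <- function(domain, D_dam = 5, D_dying = 5,
                             lambda_dam = 0.5, lambda_dying = 0.5,
                             s_dam = 1, s_dying = 1) {
  stopifnot(D_dam >= 0, D_dying >= 0, lambda_dam >= 0, lambda_dying >= 0,
            s_dam >= 0, s_dying >= 0)
  z <- matrix(0, domain$width, domain$height)
  structure(list(
    c_dam = z, c_dying = z,
    D_dam = D_dam, D_dying = D_dying,
    lambda_dam = lambda_dam, lambda_dying = lambda_dying,
    s_dam = s_dam, s_dying = s_dying
  ), class = "chemokine_fields")
}

# number of explicit-Euler substeps needed to cover dt stably
stable_substeps <- function(D, lambda, dt) {
  max(1L, as.integer(ceiling(dt * (4 * D + lambda) - 1e-12)))
}

# single-field forward Euler step, pure R (reference stencil)
euler_field_step <- function(C, domain, D, lambda, s, sources, dt, name) {
  if (4 * D + lambda > 0 && dt > 1 / (4 * D + lambda) + 1e-12) {
    stop("explicit-scheme stability bound violated for field '", name,
         "': dt = ", dt, " > 1/(4*D + lambda) = ",
         signif(1 / (4 * D + lambda), 6))
  }
  n <- domain$width * domain$height
  adm <- domain$comp_v != COMPARTMENTS[["LUMEN"]]  # length n + 1, sentinel FALSE
  C_ext <- c(as.vector(C), 0)
  lap <- numeric(n)
  for (k in seq_len(ncol(domain$nb_vn))) {
    nb <- domain$nb_vn[seq_len(n), k]
    lap <- lap + adm[nb] * (C_ext[nb] - C_ext[seq_len(n)])
  }
  newC <- as.vector(C) + dt * (D * lap - lambda * as.vector(C))
  if (length(sources)) newC[sources] <- newC[sources] + s * dt
  newC[!adm[seq_len(n)]] <- 0
  matrix(newC, domain$width)
}

#' Advance the chemokine fields by one explicit time step
#'
#' Forward-Euler update `C <- C + dt * (D * lap(C) - lambda * C + s * 1_src)`
#' with zero-flux boundaries. Errors if `dt` violates the stability bound
#' `dt <= 1/(4*D + lambda)` for either field.
#'
#' @param fields a [chemokine_fields].
#' @param domain a [tdlu_domain].
#' @param sources_dam,sources_dying linear node indices of source cells.
#' @param dt time step, hours.
#' @return Updated `chemokine_fields`.
#' @export
step_field <- function(fields, domain, sources_dam = integer(),
                       sources_dying = integer(), dt) {
  fields$c_dam <- euler_field_step(fields$c_dam, domain, fields$D_dam,
                                   fields$lambda_dam, fields$s_dam,
                                   sources_dam, dt, "c_dam")
  fields$c_dying <- euler_field_step(fields$c_dying, domain, fields$D_dying,
                                     fields$lambda_dying, fields$s_dying,
                                     sources_dying, dt, "c_dying")
  fields
}

# advance both fields across a full engine step of length dt, substepping to
# satisfy the stability bound; compiled kernel. Fields that are identically
# zero with no sources are skipped.
advance_fields <- function(fields, domain, sources_dam, sources_dying, dt) {
  adm <- matrix(as.integer(domain$compartment != COMPARTMENTS[["LUMEN"]]),
                domain$width)
  if (length(sources_dam) || any(fields$c_dam > 0)) {
    nsub <- stable_substeps(fields$D_dam, fields$lambda_dam, dt)
    fields$c_dam <- cpp_diffuse(fields$c_dam, adm, as.integer(sources_dam),
                                fields$D_dam, fields$lambda_dam, fields$s_dam,
                                dt, nsub)
  }
  if (length(sources_dying) || any(fields$c_dying > 0)) {
    nsub <- stable_substeps(fields$D_dying, fields$lambda_dying, dt)
    fields$c_dying <- cpp_diffuse(fields$c_dying, adm, as.integer(sources_dying),
                                  fields$D_dying, fields$lambda_dying,
                                  fields$s_dying, dt, nsub)
  }
  fields
}

#' Per-neighbor concentration differences at a node
#'
#' Returns `C(neighbor) - C(node)` for each in-grid, non-lumen Moore neighbor,
#' for both chemokines. These local differences drive chemotactic step
#' weights.
#'
#' @param fields a [chemokine_fields].
#' @param domain a [tdlu_domain].
#' @param node linear node index (not LUMEN).
#' @return list with `neighbors` (indices), `d_dam`, `d_dying`.
#' @export
local_gradient <- function(fields, domain, node) {
  if (domain$comp_v[node] == COMPARTMENTS[["LUMEN"]]) {
    stop("local_gradient is undefined on LUMEN nodes")
  }
  n <- domain$width * domain$height
  nb <- domain$nb_moore[node, ]
  ok <- nb <= n & domain$comp_v[nb] != COMPARTMENTS[["LUMEN"]]
  nb <- nb[ok]
  list(
    neighbors = nb,
    d_dam = fields$c_dam[nb] - fields$c_dam[node],
    d_dying = fields$c_dying[nb] - fields$c_dying[node]
  )
}

#' Mean chemokine concentrations over stromal nodes
#' @param fields a [chemokine_fields].
#' @param domain a [tdlu_domain].
#' @return named numeric vector `c(c_dam = , c_dying = )`.
#' @export
mean_stromal_concentration <- function(fields, domain) {
  s <- stromal_nodes(domain)
  c(c_dam = mean(fields$c_dam[s]), c_dying = mean(fields$c_dying[s]))
}

#' Export a chemokine field snapshot as TSV
#' Columns `node_x`, `node_y`, `c_dam`, `c_dying`.
#' @param fields a [chemokine_fields].
#' @param domain a [tdlu_domain].
#' @param path output path.
#' @export
write_field_tsv <- function(fields, domain, path) {
  idx <- seq_len(domain$width * domain$height)
  xy <- idx_to_xy(idx, domain$width)
  utils::write.table(
    data.frame(node_x = xy[, 1], node_y = xy[, 2],
               c_dam = as.vector(fields$c_dam),
               c_dying = as.vector(fields$c_dying)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
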