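# YAML run configuration, validation and command entry points.
#
# A run configuration collects the geometry, hormone, engine, chemokine,
# trafficking and sampling blocks plus the master seed. Every run writes the
# resolved configuration next to its outputs so results are reproducible
# from the output directory alone. The commands below back the thin
# command-line script shipped in inst/cli/tdlusim.

#' Default run configuration
#'
#' All tunable fields with their defaults; see the methods vignette for the
#' rationale behind each value.
#' @return nested list.
#' @export
default_run_config <- function() {
  list(
    geometry = list(n_acini = 18L, lumen_radius = 2L, acinus_spacing = 11L,
                    grid_size = 60L, stromal_margin = 3L, seed = 1L),
    hormone = list(curve_csv = NULL, follicular_len = 14, luteal_len = 14),
    engine = list(k_pro = 0.03, k_apt = 0.0021, k_dge = 0, k_kill = 0.1,
                  k_sup = 0.05, theta = 1, c_act = 0.05, chi = 30, m_rate = 4,
                  tau_lys = 12, dt = 1),
    chemokine = list(D_dam = 5, D_dying = 5, lambda_dam = 0.5,
                     lambda_dying = 0.5, s_dam = 1, s_dying = 1),
    trafficking = list(lam0_E = 1.55, alpha_E = 516, beta_E = 516,
                       lam0_R = 3.02, alpha_R = 516, lam_out = 0.12),
    run = list(n_cycles = 12L, n_reps = 10L),
    sampling = list(snapshot_days = c(5, 14, 25), snapshot_cycles = NULL),
    output_dir = "tdlusim-out",
    master_seed = 1L
  )
}

check_num <- function(cfg, block, field, min = -Inf, max = Inf,
                      allow_null = FALSE) {
  v <- cfg[[block]][[field]]
  where <- paste0(block, "$", field)
  if (is.null(v)) {
    if (allow_null) return(invisible(TRUE))
    stop("config validation: missing required field '", where, "'")
  }
  if (!is.numeric(v) || length(v) < 1 || any(is.na(v))) {
    stop("config validation: field '", where, "' must be numeric")
  }
  if (any(v < min) || any(v > max)) {
    stop("config validation: field '", where, "' out of range [",
         min, ", ", max, "]")
  }
  invisible(TRUE)
}

#' Validate a run configuration
#'
#' Checks presence, type and range of every field, with field-level error
#' messages.
#' @param cfg nested configuration list.
#' @return the configuration, invisibly.
#' @export
validate_run_config <- function(cfg) {
  need <- c("geometry", "hormone", "engine", "chemokine", "trafficking",
            "run", "sampling")
  for (b in need) {
    if (is.null(cfg[[b]])) stop("config validation: missing block '", b, "'")
  }
  check_num(cfg, "geometry", "n_acini", 1)
  check_num(cfg, "geometry", "lumen_radius", 1)
  check_num(cfg, "geometry", "acinus_spacing", 1)
  check_num(cfg, "geometry", "grid_size", 8)
  check_num(cfg, "geometry", "stromal_margin", 0)
  check_num(cfg, "hormone", "follicular_len", 0.1)
  check_num(cfg, "hormone", "luteal_len", 0.1)
  for (f in c("k_pro", "k_apt", "k_kill", "k_sup", "c_act", "chi", "m_rate",
              "tau_lys")) check_num(cfg, "engine", f, 0)
  check_num(cfg, "engine", "k_dge", 0, 1)
  check_num(cfg, "engine", "theta", 1e-12)
  check_num(cfg, "engine", "dt", 1e-9)
  for (f in c("D_dam", "D_dying", "lambda_dam", "lambda_dying", "s_dam",
              "s_dying")) check_num(cfg, "chemokine", f, 0)
  for (f in c("lam0_E", "alpha_E", "beta_E", "lam0_R", "alpha_R", "lam_out")) {
    check_num(cfg, "trafficking", f, 0)
  }
  check_num(cfg, "run", "n_cycles", 1)
  check_num(cfg, "run", "n_reps", 1)
  if (is.null(cfg$master_seed)) {
    stop("config validation: missing required field 'master_seed'")
  }
  invisible(cfg)
}

#' Read and validate a YAML run configuration
#'
#' Missing fields fall back to [default_run_config()] values block-wise.
#' @param path YAML file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (b in names(user)) {
    if (is.list(cfg[[b]]) && is.list(user[[b]])) {
      for (f in names(user[[b]])) cfg[[b]][[f]] <- user[[b]][[f]]
    } else {
      cfg[[b]] <- user[[b]]
    }
  }
  validate_run_config(cfg)
  cfg
}

config_to_objects <- function(cfg) {
  g <- cfg$geometry
  domain <- build_tdlu(n_acini = g$n_acini, lumen_radius = g$lumen_radius,
                       acinus_spacing = g$acinus_spacing,
                       grid_size = g$grid_size, seed = g$seed,
                       stromal_margin = g$stromal_margin)
  profile <- if (!is.null(cfg$hormone$curve_csv)) {
    read_hormone_csv(cfg$hormone$curve_csv,
                     follicular_len = cfg$hormone$follicular_len,
                     luteal_len = cfg$hormone$luteal_len,
                     theta = cfg$engine$theta)
  } else {
    default_profile(theta = cfg$engine$theta)
  }
  if (cfg$hormone$follicular_len != profile$follicular_len) {
    profile <- rescale_follicular(profile, cfg$hormone$follicular_len)
  }
  e <- cfg$engine
  params <- simulation_params(
    k_pro = e$k_pro, k_apt = e$k_apt, k_dge = e$k_dge, k_kill = e$k_kill,
    k_sup = e$k_sup, theta = e$theta, c_act = e$c_act, chi = e$chi,
    m_rate = e$m_rate, tau_lys = e$tau_lys, dt = e$dt,
    chemokine = cfg$chemokine,
    trafficking = do.call(trafficking_params, cfg$trafficking)
  )
  sim_config(domain, profile, params, master_seed = cfg$master_seed,
             snapshot_days = cfg$sampling$snapshot_days,
             snapshot_cycles = cfg$sampling$snapshot_cycles)
}

write_resolved_config <- function(cfg, dir) {
  cfg$package_version <- as.character(utils::packageVersion("tdlusim"))
  yaml::write_yaml(cfg, file.path(dir, "resolved_config.yaml"))
}

#' Run a full simulation experiment from a configuration
#'
#' Writes per-replicate time-series CSV, pooled series CSV, snapshot TSVs,
#' the domain TSV and the resolved configuration into the output directory.
#'
#' @param cfg validated configuration list (or a YAML path).
#' @return list as returned by [run_replicates()], invisibly.
#' @export
cmd_simulate <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- config_to_objects(cfg)
  reps <- run_replicates(sc, n_reps = cfg$run$n_reps,
                         n_cycles = cfg$run$n_cycles)
  for (r in seq_along(reps$series)) {
    utils::write.csv(reps$series[[r]],
                     file.path(cfg$output_dir, sprintf("series_rep%02d.csv", r)),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(reps$pooled)) {
    utils::write.csv(reps$pooled, file.path(cfg$output_dir, "series_pooled.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  for (r in seq_along(reps$snapshots)) {
    for (k in seq_along(reps$snapshots[[r]])) {
      sn <- reps$snapshots[[r]][[k]]
      utils::write.table(sn, file.path(cfg$output_dir,
                                       sprintf("snapshot_rep%02d_%03d.tsv", r, k)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  write_domain_tsv(sc$domain, file.path(cfg$output_dir, "domain.tsv"))
  write_resolved_config(cfg, cfg$output_dir)
  invisible(reps)
}

#' Calibrate trafficking from a fixture and write the result as JSON
#'
#' @param fixture_csv calibration fixture path (default: packaged fixture).
#' @param cfg configuration (list or YAML path).
#' @param ... passed to [calibrate_trafficking()].
#' @return the calibrated [trafficking_params()], invisibly.
#' @export
cmd_calibrate <- function(fixture_csv = NULL, cfg = default_run_config(), ...) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  targets <- if (is.null(fixture_csv)) {
    make_calibration_fixture()
  } else {
    read_calibration_csv(fixture_csv)
  }
  sc <- config_to_objects(cfg)
  tp <- calibrate_trafficking(targets, sc$domain, sc$profile, sc$params,
                              seed = cfg$master_seed, ...)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    c(unclass(tp), list(residual = attr(tp, "residual"),
                        achieved = as.list(attr(tp, "achieved")))),
    file.path(cfg$output_dir, "trafficking_calibrated.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(tp)
}

#' Spatial statistics of a snapshot TSV
#'
#' Computes g(r), its power-law fit and cluster statistics for the immune
#' cells of a snapshot written by [cmd_simulate()].
#'
#' @param snapshot_tsv snapshot path.
#' @param domain_tsv domain path written next to it.
#' @param out_prefix output path prefix (writes `<prefix>_rdf.csv` and
#'   `<prefix>_clusters.json`); `NULL` skips writing.
#' @return list `(rdf_fit, clusters)`.
#' @export
cmd_stats <- function(snapshot_tsv, domain_tsv = NULL, out_prefix = NULL) {
  sn <- tryCatch(
    utils::read.table(snapshot_tsv, sep = "\t", header = TRUE),
    error = function(e) stop("malformed snapshot TSV '", snapshot_tsv, "': ",
                             conditionMessage(e))
  )
  if (!all(c("x", "y") %in% names(sn))) {
    stop("snapshot TSV must contain columns x and y")
  }
  # reconstruct a minimal domain solely for distances if none is given
  domain <- if (!is.null(domain_tsv)) {
    m <- read_domain_tsv(domain_tsv)
    rebuild_domain_from_matrix(m)
  } else {
    stop("cmd_stats requires the domain TSV written by cmd_simulate")
  }
  rdf <- radial_distribution(cbind(sn$x, sn$y), domain)
  fit <- fit_power_law(rdf)
  cl <- cluster_stats(cbind(sn$x, sn$y), domain)
  if (!is.null(out_prefix)) {
    write_rdf_csv(fit, paste0(out_prefix, "_rdf.csv"))
    write_cluster_json(cl, paste0(out_prefix, "_clusters.json"))
  }
  list(rdf_fit = fit, clusters = cl)
}

# rebuild a tdlu_domain (minus acinus metadata) from a compartment matrix
rebuild_domain_from_matrix <- function(m) {
  dom <- structure(list(
    width = nrow(m), height = ncol(m),
    compartment = m,
    comp_v = c(as.integer(m), COMPARTMENTS[["LUMEN"]]),
    tdlu_polygon = NULL,
    nb_moore = neighbor_table(nrow(m), ncol(m), moore = TRUE),
    nb_vn = neighbor_table(nrow(m), ncol(m), moore = FALSE),
    acini = NULL,
    n_epithelial = sum(m == COMPARTMENTS[["LUMINAL_EPITHELIUM"]] |
                         m == COMPARTMENTS[["MYOEPITHELIUM"]]),
    cache = new.env(parent = emptyenv())
  ), class = "tdlu_domain")
  dom$dist_epi <- distance_to_epithelium(dom)
  dom
}

#' Run a parameter sweep from a manifest
#'
#' @param manifest_json JSON with a `grid` array of parameter points and
#'   optional `n_reps`, `n_cycles`.
#' @param cfg base configuration (list or YAML path).
#' @param out_csv regime map output path (`NULL` skips writing).
#' @return classified sweep result, invisibly.
#' @export
cmd_sweep <- function(manifest_json, cfg = default_run_config(),
                      out_csv = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  man <- jsonlite::read_json(manifest_json, simplifyVector = TRUE)
  if (is.null(man$grid)) stop("sweep manifest must contain a 'grid' table")
  sc <- config_to_objects(cfg)
  sw <- sweep_parameters(as.data.frame(man$grid), sc,
                         n_reps = man$n_reps %||% cfg$run$n_reps,
                         n_cycles = man$n_cycles %||% cfg$run$n_cycles)
  sw <- classify_sweep(sw)
  if (!is.null(out_csv)) write_sweep_csv(sw, out_csv)
  invisible(sw)
}
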