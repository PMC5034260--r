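# Replicate experiments, parameter sweeps and regime classification.
#
# The in-silico protocol runs, for each parameter constellation, independent
# seeded replicates of 12 menstrual cycles (about one year) and pools the
# statistics. Sweeps vary the damage probability k_dge, the killing rate
# k_kill, the hormone level theta and the follicular phase length. Each sweep
# point is summarized into a regime report; the classifier labels points as
# PHYSIOLOGICAL (damage still on the linear segment of the damage-vs-k_dge
# curve and inflammation resolves within the cycle), CHRONIC (the infiltrate
# never returns to the baseline level within any cycle) or SEVERE
# (everything in between).

#' Assemble a simulation configuration
#'
#' @param domain a [tdlu_domain].
#' @param profile a [hormone_profile].
#' @param params a [simulation_params()].
#' @param master_seed master seed; replicate r runs with a counter-derived
#'   stream seed so sweeps are reproducible point-by-point.
#' @param snapshot_days optional days-of-cycle for immune point snapshots.
#' @param snapshot_cycles optional cycle subset for snapshots.
#' @return a `sim_config` list.
#' @export
sim_config <- function(domain, profile = default_profile(),
                       params = simulation_params(), master_seed = 1,
                       snapshot_days = NULL, snapshot_cycles = NULL) {
  structure(list(domain = domain, profile = profile, params = params,
                 master_seed = master_seed, snapshot_days = snapshot_days,
                 snapshot_cycles = snapshot_cycles),
            class = "sim_config")
}

replicate_seed <- function(master, rep) {
  as.integer((as.numeric(master) * 48271 + 2654435 * rep) %% 2147483647)
}

#' Run independent seeded replicates of one configuration
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicates (default 10).
#' @param n_cycles cycles per replicate (default 12).
#' @return list with `series` (per-replicate data frames), `snapshots`
#'   (per-replicate lists), `pooled` (per-time mean/min/max of the relative
#'   numbers), `excluded` (replicates with epithelial extinction, dropped
#'   from pooling) and `seeds`.
#' @export
run_replicates <- function(config, n_reps = 10, n_cycles = 12) {
  seeds <- vapply(seq_len(n_reps), function(r) replicate_seed(config$master_seed, r), 0L)
  runs <- lapply(seq_len(n_reps), function(r) {
    run_simulation(config$domain, config$profile, config$params,
                   n_cycles = n_cycles, seed = seeds[r],
                   snapshot_days = config$snapshot_days,
                   snapshot_cycles = config$snapshot_cycles)
  })
  series <- lapply(runs, `[[`, "series")
  extinct <- which(vapply(series, function(s) any(s$n_epi == 0), TRUE))
  if (length(extinct)) {
    warning("epithelial extinction in replicate(s) ",
            paste(extinct, collapse = ", "), "; excluded from pooling")
  }
  keep <- setdiff(seq_len(n_reps), extinct)
  pooled <- NULL
  if (length(keep)) {
    vars <- c("n_epi", "rel_eff", "rel_reg", "rel_damaged", "pi_sample",
              "ai_sample")
    pooled <- data.frame(t_h = series[[keep[1]]]$t_h)
    for (v in vars) {
      m <- vapply(keep, function(r) series[[r]][[v]], series[[keep[1]]][[v]])
      m <- matrix(m, ncol = length(keep))
      pooled[[paste0(v, "_mean")]] <- rowMeans(m)
      pooled[[paste0(v, "_min")]] <- apply(m, 1, min)
      pooled[[paste0(v, "_max")]] <- apply(m, 1, max)
    }
  }
  list(series = series, snapshots = lapply(runs, `[[`, "snapshots"),
       pooled = pooled, excluded = extinct, seeds = seeds)
}

#' Per-phase effector means and the overall regulatory mean
#'
#' Windows follow the calibration protocol: follicular day 1-11, in-between
#' day 11-17, luteal day 17-28 (day-of-cycle), pooled across all cycles of
#' the supplied series.
#'
#' @param ts a series data frame (or several replicates row-bound together).
#' @param cycle_len cycle length in days (default 28).
#' @return named vector `follicular`, `inbetween`, `luteal`,
#'   `regulatory_all`.
#' @export
phase_means <- function(ts, cycle_len = 28) {
  if (max(ts$t_h) < cycle_len * 24) stop("series spans less than one cycle")
  ph <- phase_window(ts$t_h, cycle_len)
  c(follicular = mean(ts$rel_eff[ph == "follicular"]),
    inbetween = mean(ts$rel_eff[ph == "inbetween"]),
    luteal = mean(ts$rel_eff[ph == "luteal"]),
    regulatory_all = mean(ts$rel_reg))
}

#' Proliferation/apoptosis index read-out with analytic expectations
#'
#' `pi_sample(t)` is the number of division-committed cells in the last hour
#' per 1000 epithelial cells (the Ki-67 analogue); `ai_sample` counts
#' apoptosis entries. Expectations are `1000 * k_pro * theta * f_PI(t)` and
#' `1000 * k_apt * theta * f_AI(t)`.
#'
#' @param ts a series data frame from [run_simulation()].
#' @param profile the [hormone_profile] used.
#' @param params the [simulation_params()] used.
#' @return data frame `t_h, pi_sample, ai_sample, pi_expected, ai_expected`.
#' @export
pi_ai_readout <- function(ts, profile, params) {
  t_day <- ts$t_h / 24
  data.frame(
    t_h = ts$t_h,
    pi_sample = ts$pi_sample,
    ai_sample = ts$ai_sample,
    pi_expected = 1000 * params$k_pro * params$theta *
      profile_value(profile, t_day, "f_pi"),
    ai_expected = 1000 * params$k_apt * params$theta *
      profile_value(profile, t_day, "f_ai")
  )
}

# pooled summaries of one sweep point
summarize_point <- function(reps, config, n_cycles, point) {
  pooled <- reps$pooled
  cl <- cycle_length(config$profile)
  rel_imm <- pooled$rel_eff_mean + pooled$rel_reg_mean
  hoc <- round(pooled$t_h %% (cl * 24), 6)  # hour of cycle
  by_hoc <- tapply(rel_imm, hoc, mean)
  cyc <- floor((pooled$t_h - config$params$dt / 2) / (cl * 24)) + 1
  # the first cycle is the initialization transient (the immune compartment
  # fills from empty); regime criteria use the subsequent cycles
  keep_cyc <- cyc > 1 | max(cyc) == 1
  cyc_min <- as.numeric(tapply(rel_imm[keep_cyc], cyc[keep_cyc], min))
  cyc_max <- as.numeric(tapply(rel_imm[keep_cyc], cyc[keep_cyc], max))
  clus <- unlist(lapply(reps$snapshots, function(snl) {
    vapply(snl, function(sn) {
      cluster_stats(cbind(sn$x, sn$y), config$domain)$n_clusters
    }, 0)
  }))
  list(
    k_dge = point$k_dge %||% config$params$k_dge,
    k_kill = point$k_kill %||% config$params$k_kill,
    theta = point$theta %||% config$params$theta,
    follicular_len = point$follicular_len %||% config$profile$follicular_len,
    mean_rel_damaged = mean(pooled$rel_damaged_mean),
    mean_rel_eff = mean(pooled$rel_eff_mean),
    mean_rel_reg = mean(pooled$rel_reg_mean),
    mean_rel_immune = mean(rel_imm),
    amplitude_immune = max(by_hoc) - min(by_hoc),
    reg_minus_eff = mean(pooled$rel_reg_mean - pooled$rel_eff_mean),
    cycle_min_rel_imm = cyc_min,
    cycle_max_rel_imm = cyc_max,
    sd_rel_imm = stats::sd(rel_imm),
    max_rel_imm = max(rel_imm),
    mean_n_clusters = if (length(clus)) mean(clus) else NA_real_,
    n_excluded = length(reps$excluded),
    snapshots = reps$snapshots,
    regime = NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a parameter sweep
#'
#' @param grid data frame; recognised columns: `k_dge`, `k_kill`, `theta`,
#'   `follicular_len`. Each row is one parameter constellation.
#' @param config base [sim_config()]; per-row values override its parameters,
#'   and `follicular_len` rescales the hormone profile via
#'   [rescale_follicular()].
#' @param n_reps replicates per point.
#' @param n_cycles cycles per replicate.
#' @return list with `results` (one row per grid point, regime unlabelled --
#'   see [classify_sweep()]), `reports` (full per-point summaries) and
#'   `failures` (error messages per failed point, if any).
#' @export
sweep_parameters <- function(grid, config, n_reps = 10, n_cycles = 12) {
  reports <- vector("list", nrow(grid))
  failures <- list()
  for (i in seq_len(nrow(grid))) {
    point <- as.list(grid[i, , drop = FALSE])
    res <- tryCatch({
      cfg <- config
      if (!is.null(point$k_dge)) cfg$params$k_dge <- point$k_dge
      if (!is.null(point$k_kill)) cfg$params$k_kill <- point$k_kill
      if (!is.null(point$theta)) cfg$params$theta <- point$theta
      if (!is.null(point$follicular_len) &&
          point$follicular_len != cfg$profile$follicular_len) {
        cfg$profile <- rescale_follicular(cfg$profile, point$follicular_len)
      }
      cfg$master_seed <- replicate_seed(config$master_seed, 7777 + i)
      reps <- run_replicates(cfg, n_reps = n_reps, n_cycles = n_cycles)
      summarize_point(reps, cfg, n_cycles, point)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(i)]] <- conditionMessage(res)
      reports[[i]] <- NULL
    } else {
      reports[[i]] <- res
    }
  }
  ok <- !vapply(reports, is.null, TRUE)
  results <- do.call(rbind, lapply(reports[ok], function(r) {
    data.frame(r[c("k_dge", "k_kill", "theta", "follicular_len",
                   "mean_rel_damaged", "mean_rel_eff", "mean_rel_reg",
                   "mean_rel_immune", "amplitude_immune", "reg_minus_eff",
                   "mean_n_clusters", "regime")])
  }))
  list(results = results, reports = reports[ok], failures = failures)
}

#' Classify one sweep point into an inflammation regime
#'
#' PHYSIOLOGICAL: the point sits on the linear segment of the
#' damage-vs-k_dge curve (relative residual from the low-k_dge linear fit
#' below `resid_tol`) and the within-cycle minimum infiltrate returns to the
#' baseline band (baseline mean + 2 SD) in at least half of the cycles.
#' CHRONIC: the within-cycle minimum infiltrate exceeds the baseline maximum
#' in every cycle (inflammation never resolves). SEVERE: otherwise.
#' A `k_dge = 0` point is PHYSIOLOGICAL by definition.
#'
#' @param report a per-point summary from [sweep_parameters()]`$reports`.
#' @param baseline the `k_dge = 0` report with the same `(k_kill, theta,
#'   follicular_len)`.
#' @param linear_resid relative residual of the point from the low-k_dge
#'   linear fit (computed by [classify_sweep()]).
#' @param resid_tol linearity tolerance (default 0.1).
#' @return one of `"PHYSIOLOGICAL"`, `"SEVERE"`, `"CHRONIC"`.
#' @export
classify_regime <- function(report, baseline, linear_resid = 0,
                            resid_tol = 0.1) {
  if (is.null(baseline)) stop("classify_regime: missing k_dge = 0 baseline")
  if (report$k_dge == 0) return("PHYSIOLOGICAL")
  if (all(report$cycle_min_rel_imm > baseline$max_rel_imm)) return("CHRONIC")
  band_hi <- baseline$mean_rel_immune + 2 * baseline$sd_rel_imm
  resolves <- mean(report$cycle_min_rel_imm <= band_hi) >= 0.5
  if (is.finite(linear_resid) && linear_resid < resid_tol && resolves) {
    return("PHYSIOLOGICAL")
  }
  "SEVERE"
}

#' Label every point of a sweep with its inflammation regime
#'
#' Groups points by `(k_kill, theta, follicular_len)`; within each group the
#' damage-vs-k_dge linear reference is fitted through the origin on the three
#' smallest k_dge values, and every point's relative residual from that line
#' feeds [classify_regime()].
#'
#' @param sweep result of [sweep_parameters()].
#' @param resid_tol linearity tolerance (default 0.1).
#' @return `sweep` with `results$regime` and per-report `regime` filled in.
#' @export
classify_sweep <- function(sweep, resid_tol = 0.1) {
  reports <- sweep$reports
  key <- vapply(reports, function(r) {
    paste(r$k_kill, r$theta, r$follicular_len, sep = "|")
  }, "")
  for (k in unique(key)) {
    idx <- which(key == k)
    kd <- vapply(reports[idx], `[[`, 0, "k_dge")
    dmg <- vapply(reports[idx], `[[`, 0, "mean_rel_damaged")
    base_i <- idx[which(kd == 0)[1]]
    baseline <- if (is.na(base_i)) NULL else reports[[base_i]]
    ord <- order(kd)
    low <- ord[seq_len(min(3L, length(ord)))]
    slope <- if (sum(kd[low]^2) > 0) sum(kd[low] * dmg[low]) / sum(kd[low]^2) else 0
    for (j in seq_along(idx)) {
      pred <- slope * kd[j]
      rel_resid <- if (pred > 0) abs(dmg[j] - pred) / pred else 0
      reports[[idx[j]]]$regime <- classify_regime(reports[[idx[j]]], baseline,
                                                  rel_resid, resid_tol)
    }
  }
  sweep$reports <- reports
  sweep$results$regime <- vapply(reports, `[[`, "", "regime")
  sweep
}

#' Write sweep results as CSV
#' @param sweep a (classified) sweep result.
#' @param path output path.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep$results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
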