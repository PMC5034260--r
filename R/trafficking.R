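# Chemokine-dependent immune cell trafficking.
#
# Vasculature is assumed homogeneously distributed in the stroma, so immune
# cells enter on any free stromal node and leave from wherever they sit.
# Influx intensities are linear in the mean chemokine concentrations over
# stromal nodes: the damaged-cell chemokine recruits both effector and
# regulatory cells, the dying-cell ("find-me") chemokine recruits effectors
# only. Entries are domain-level Poisson draws; each INACTIVE or
# PERM_INACTIVE immune cell exits with per-step probability
# 1 - exp(-lam_out * dt). ACTIVE cells never exit.

#' Trafficking parameters
#'
#' @param lam0_E,lam0_R baseline influx intensities, cells per hour per domain.
#' @param alpha_E,alpha_R coupling of influx to the mean damaged-cell
#'   chemokine, cells per hour per concentration unit.
#' @param beta_E coupling of effector influx to the mean dying-cell
#'   chemokine. Regulatory influx has no dying-cell term.
#' @param lam_out per-cell efflux rate for non-ACTIVE immune cells, per hour.
#'
#' Defaults are the output of [calibrate_trafficking()] against the packaged
#' per-phase targets on the default ~500-epithelial-cell TDLU; the damage
#' couplings `alpha_E`/`alpha_R`, which the zero-damage baseline cannot
#' constrain, default to the calibrated dying-signal coupling `beta_E`
#' (equal sensitivity to both inflammatory chemokines).
#' @return A `trafficking_params` list.
#' @export
trafficking_params <- function(lam0_E = 1.55, alpha_E = 516, beta_E = 516,
                               lam0_R = 3.02, alpha_R = 516, lam_out = 0.12) {
  stopifnot(lam0_E >= 0, alpha_E >= 0, beta_E >= 0, lam0_R >= 0,
            alpha_R >= 0, lam_out >= 0)
  structure(list(lam0_E = unname(lam0_E), alpha_E = unname(alpha_E),
                 beta_E = unname(beta_E), lam0_R = unname(lam0_R),
                 alpha_R = unname(alpha_R), lam_out = unname(lam_out)),
            class = "trafficking_params")
}

#' Influx intensities from the current chemokine fields
#'
#' `lambda_E = lam0_E + alpha_E * <C_dam> + beta_E * <C_dying>` and
#' `lambda_R = lam0_R + alpha_R * <C_dam>`, with `<.>` the mean over stromal
#' nodes. Deterministic.
#'
#' @param fields a [chemokine_fields].
#' @param domain a [tdlu_domain].
#' @param params a [trafficking_params()].
#' @return named numeric vector `c(lambda_E = , lambda_R = )`.
#' @export
influx_intensities <- function(fields, domain, params) {
  m <- mean_stromal_concentration(fields, domain)
  c(lambda_E = params$lam0_E + params$alpha_E * m[["c_dam"]] +
      params$beta_E * m[["c_dying"]],
    lambda_R = params$lam0_R + params$alpha_R * m[["c_dam"]])
}

#' Apply one trafficking update (end of an engine step)
#'
#' Removes each non-ACTIVE immune cell with probability
#' `1 - exp(-lam_out * dt)`, then draws Poisson(lambda * dt) entries per
#' immune type and places each on a uniformly random free stromal node.
#' Entries that cannot be placed are discarded with a warning.
#'
#' @param sim a `tdlu_sim`.
#' @param params trafficking parameters (defaults to the configured block).
#' @return list `(n_in, n_out)`, invisibly.
#' @export
apply_trafficking <- function(sim, params = sim$params$trafficking) {
  dt <- sim$params$dt
  imm <- sim$imm_ids
  n_out <- 0L
  if (length(imm) && params$lam_out > 0) {
    cand <- imm[sim$state[imm] != IMM_STATES[["ACTIVE"]]]
    if (length(cand)) {
      p_out <- 1 - exp(-params$lam_out * dt)
      gone <- cand[stats::runif(length(cand)) < p_out]
      for (id in gone) remove_cell(sim, id)
      sim$imm_ids <- setdiff(imm, gone)
      n_out <- length(gone)
    }
  }
  lam <- influx_intensities(sim$fields, sim$domain, params)
  n_E <- stats::rpois(1, lam[["lambda_E"]] * dt)
  n_R <- stats::rpois(1, lam[["lambda_R"]] * dt)
  n_in <- 0L
  if (n_E + n_R > 0) {
    free <- sim$stromal[sim$occ[sim$stromal] == 0L]
    n_place <- min(n_E + n_R, length(free))
    if (n_place < n_E + n_R) {
      warning("trafficking: ", n_E + n_R - n_place,
              " immune cell entr", if (n_E + n_R - n_place > 1) "ies" else "y",
              " discarded (no free stromal node)")
    }
    if (n_place > 0) {
      # type assignment follows the draw order: effectors first
      types <- c(rep(CELL_TYPES[["EFFECTOR"]], n_E),
                 rep(CELL_TYPES[["REGULATORY"]], n_R))[seq_len(n_place)]
      nodes <- if (length(free) == 1L) free else sample(free, n_place)
      for (k in seq_len(n_place)) {
        id <- add_cell(sim, nodes[k], types[k], IMM_STATES[["INACTIVE"]])
        sim$imm_ids <- c(sim$imm_ids, id)
      }
      n_in <- n_place
    }
  }
  invisible(list(n_in = n_in, n_out = n_out))
}

# --- calibration -------------------------------------------------------------

# Expected effector/regulatory occupancy under the discrete birth-death
# recursion E[N(t+dt)] = E[N(t)] * (1 - p_out) + lambda(t) * dt, given a
# measured mean dying-cell chemokine trace. Returns the two linear basis
# responses: h0 (response to unit lam0) and h1 (response to unit beta_E).
basis_responses <- function(c_dying_trace, dt, lam_out) {
  p_out <- 1 - exp(-lam_out * dt)
  nT <- length(c_dying_trace)
  h0 <- numeric(nT)
  h1 <- numeric(nT)
  a0 <- a1 <- 0
  for (i in seq_len(nT)) {
    a0 <- a0 * (1 - p_out) + dt
    a1 <- a1 * (1 - p_out) + c_dying_trace[i] * dt
    h0[i] <- a0
    h1[i] <- a1
  }
  list(h0 = h0, h1 = h1)
}

phase_window <- function(t_h, cycle_len) {
  day <- (t_h / 24) %% cycle_len
  ifelse(day >= 1 & day < 11, "follicular",
         ifelse(day >= 11 & day < 17, "inbetween",
                ifelse(day >= 17, "luteal", "menses")))
}

#' Calibrate trafficking parameters against per-phase targets
#'
#' Fits `(lam0_E, beta_E, lam0_R, lam_out)` so that the baseline simulation
#' (k_dge = 0, hence no damaged-cell chemokine) reproduces the target mean
#' relative effector numbers in the follicular (day 1-11), in-between (day
#' 11-17) and luteal (day 17-28) windows plus the overall regulatory mean.
#'
#' Because immune cells do not affect epithelial dynamics at k_dge = 0, the
#' expected effector count is linear in `(lam0_E, beta_E)` given the
#' dying-cell chemokine trace of a pilot run; the fit solves that linear
#' system over a grid of `lam_out` values and then refines all four
#' parameters by multiplicative coordinate search against simulated phase
#' means (`n_reps` replicates x `n_cycles` cycles per evaluation, fixed
#' seeds).
#'
#' @param targets calibration fixture: data frame with columns
#'   `phase` (`follicular`, `inbetween`, `luteal`, `regulatory_all`),
#'   `target_mean`, `tolerance` (see [make_calibration_fixture()]).
#' @param domain a [tdlu_domain].
#' @param profile a [hormone_profile].
#' @param params a [simulation_params()] (its `k_dge` is forced to 0).
#' @param n_reps replicates per objective evaluation (>= 3).
#' @param n_cycles cycles per replicate (default 12).
#' @param lam_out_grid efflux rates tried in the linear stage.
#' @param max_evals coordinate-search budget (simulation evaluations).
#' @param seed master seed for the pilot and objective replicates.
#' @return a [trafficking_params()] with attributes `residual` (weighted
#'   root-mean-square residual in tolerance units) and `achieved` (named
#'   phase means of the final evaluation).
#' @export
calibrate_trafficking <- function(targets, domain, profile,
                                  params = simulation_params(),
                                  n_reps = 3, n_cycles = 12,
                                  lam_out_grid = c(0.03, 0.05, 0.08, 0.12),
                                  max_evals = 8, seed = 1) {
  stopifnot(all(c("phase", "target_mean", "tolerance") %in% names(targets)))
  tg <- function(ph) targets$target_mean[match(ph, targets$phase)]
  tol <- function(ph) targets$tolerance[match(ph, targets$phase)]
  phases <- c("follicular", "inbetween", "luteal")
  t_eff <- vapply(phases, tg, 0)
  w_eff <- 1 / vapply(phases, tol, 0)^2
  t_reg <- tg("regulatory_all")

  if (all(c(t_eff, t_reg) == 0)) {
    # degenerate exact fit: no influx at all
    return(structure(trafficking_params(lam0_E = 0, alpha_E = 0, beta_E = 0,
                                        lam0_R = 0, alpha_R = 0,
                                        lam_out = params$trafficking$lam_out),
                     residual = 0, achieved = c(t_eff, regulatory_all = 0)))
  }

  params$k_dge <- 0
  dt <- params$dt
  cl <- cycle_length(profile)

  # pilot: epithelial dynamics and the dying-cell chemokine trace do not
  # depend on trafficking, so run it with no influx at all
  p0 <- params
  p0$trafficking <- trafficking_params(0, 0, 0, 0, 0, 0)
  traces <- lapply(seq_len(n_reps), function(r) {
    pilot_trace(domain, profile, p0, n_cycles, calib_seed(seed, r))
  })
  c_dying <- rowMeans(do.call(cbind, lapply(traces, `[[`, "c_dying")))
  n_epi <- rowMeans(do.call(cbind, lapply(traces, `[[`, "n_epi")))
  t_h <- traces[[1]]$t_h
  ph <- phase_window(t_h, cl)

  phase_mean <- function(x, w) vapply(phases, function(p) mean(x[w == p]), 0)

  best <- NULL
  for (lam_out in lam_out_grid) {
    b <- basis_responses(c_dying, dt, lam_out)
    A <- cbind(phase_mean(b$h0 / n_epi, ph), phase_mean(b$h1 / n_epi, ph))
    fit <- stats::lm.wfit(A, t_eff, w_eff)
    coefs <- pmax(ifelse(is.na(fit$coefficients), 0, fit$coefficients), 0)
    pred <- as.vector(A %*% coefs)
    resid <- sqrt(mean(((pred - t_eff) * sqrt(w_eff))^2))
    if (is.null(best) || resid < best$resid) {
      p_out <- 1 - exp(-lam_out * dt)
      best <- list(lam_out = lam_out, lam0_E = coefs[1], beta_E = coefs[2],
                   lam0_R = t_reg * mean(n_epi) * p_out / dt, resid = resid)
    }
  }

  mk <- function(v) trafficking_params(
    lam0_E = v[1], alpha_E = params$trafficking$alpha_E, beta_E = v[2],
    lam0_R = v[3], alpha_R = params$trafficking$alpha_R, lam_out = v[4]
  )
  objective <- function(v) {
    pp <- params
    pp$trafficking <- mk(v)
    means <- simulated_phase_means(domain, profile, pp, n_reps, n_cycles, seed)
    # weighted RMS residual in tolerance units over the four targets
    z <- c((means[phases] - t_eff) / vapply(phases, tol, 0),
           (means[["regulatory_all"]] - t_reg) / tol("regulatory_all"))
    list(resid = sqrt(mean(z^2)), means = means)
  }

  v <- c(best$lam0_E, best$beta_E, best$lam0_R, best$lam_out)
  cur <- objective(v)
  evals <- 1L
  # stop early once every phase mean sits within half its tolerance
  within <- function(means) {
    all(abs(means[phases] - t_eff) <= vapply(phases, tol, 0) / 2) &&
      abs(means[["regulatory_all"]] - t_reg) <= tol("regulatory_all") / 2
  }
  if (!within(cur$means)) {
    step <- 1.2
    k <- 1L
    while (evals < max_evals) {
      improved <- FALSE
      for (i in seq_along(v)) {
        for (f in c(step, 1 / step)) {
          if (evals >= max_evals) break
          vv <- v
          vv[i] <- vv[i] * f
          cand <- objective(vv)
          evals <- evals + 1L
          if (cand$resid < cur$resid) {
            v <- vv
            cur <- cand
            improved <- TRUE
            break
          }
        }
      }
      if (within(cur$means) || !improved) break
      k <- k + 1L
    }
  }

  if (cur$resid > 2) {
    stop("calibration did not converge: weighted residual ",
         signif(cur$resid, 4), " tolerance units; best parameters lam0_E = ",
         signif(v[1], 4), ", beta_E = ", signif(v[2], 4), ", lam0_R = ",
         signif(v[3], 4), ", lam_out = ", signif(v[4], 4))
  }
  structure(mk(v), residual = cur$resid, achieved = cur$means)
}

calib_seed <- function(master, rep) {
  as.integer((as.numeric(master) * 7919 + 104729 * rep) %% 2147483647)
}

# trace of the mean stromal dying-cell chemokine and the epithelial count
pilot_trace <- function(domain, profile, params, n_cycles, seed) {
  set.seed(seed)
  sim <- new_simulation(domain, profile, params)
  n_steps <- as.integer(round(n_cycles * cycle_length(profile) * 24 / params$dt))
  c_dying <- numeric(n_steps)
  n_epi <- numeric(n_steps)
  t_h <- numeric(n_steps)
  stromal <- stromal_nodes(domain)
  for (i in seq_len(n_steps)) {
    step_simulation(sim)
    c_dying[i] <- mean(sim$fields$c_dying[stromal])
    n_epi[i] <- length(sim$epi_ids)
    t_h[i] <- sim$t_h
  }
  list(c_dying = c_dying, n_epi = n_epi, t_h = t_h)
}

# pooled per-phase effector means plus the overall regulatory mean from
# n_reps seeded baseline replicates
simulated_phase_means <- function(domain, profile, params, n_reps, n_cycles,
                                  seed) {
  cl <- cycle_length(profile)
  runs <- lapply(seq_len(n_reps), function(r) {
    run_simulation(domain, profile, params, n_cycles = n_cycles,
                   seed = calib_seed(seed, 1000 + r))$series
  })
  s <- do.call(rbind, runs)
  ph <- phase_window(s$t_h, cl)
  c(follicular = mean(s$rel_eff[ph == "follicular"]),
    inbetween = mean(s$rel_eff[ph == "inbetween"]),
    luteal = mean(s$rel_eff[ph == "luteal"]),
    regulatory_all = mean(s$rel_reg))
}
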