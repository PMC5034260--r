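# Stochastic per-time-step update of all cells.
#
# Each step: (1) checkpoint phase on the step-start state -- immune
# activation/inactivation by the damaged-cell chemokine, contact killing of
# damaged epithelial cells by active effectors, permanent inactivation of
# active effectors by adjacent active regulatory cells, and lysis of expired
# dying cells; (2) action phase -- motility (immune), proliferation
# (epithelial) and apoptosis (normal epithelial) attempted over one fresh
# random permutation of candidate cells, processes per cell tried in random
# order until one executes; (3) chemokine field update; (4) immune cell
# trafficking. Rate r over contact count k maps to a per-step probability
# 1 - exp(-r * k * dt), so proportional-hazard statements hold exactly.

#' Cell type codes
#' @format Named integer vector.
#' @export
CELL_TYPES <- c(EPI_LUMINAL = 1L, EPI_MYO = 2L, EFFECTOR = 3L, REGULATORY = 4L)

#' Epithelial state codes
#' @format Named integer vector.
#' @export
EPI_STATES <- c(NORMAL = 1L, DAMAGED = 2L, DYING = 3L)

#' Immune state codes
#' @format Named integer vector.
#' @export
IMM_STATES <- c(ACTIVE = 1L, INACTIVE = 2L, PERM_INACTIVE = 3L)

is_epithelial <- function(type) type <= CELL_TYPES[["EPI_MYO"]]

#' Simulation parameters
#'
#' All rates are per hour; the time step `dt` defaults to 1 h so per-step
#' event probabilities stay well below 1 at physiological rates.
#'
#' @param k_pro baseline epithelial division rate (0.03 /h).
#' @param k_apt baseline apoptosis rate (0.0021 /h).
#' @param k_dge probability that the daughter of a normal cell is damaged.
#' @param k_kill killing rate per adjacent active effector.
#' @param k_sup suppression rate per adjacent active regulatory cell.
#' @param theta positive hormone level scaling the turnover curves.
#' @param c_act chemokine activation threshold (concentration units,
#'   inclusive).
#' @param chi chemotaxis sensitivity (>= 0; 0 = pure random walk).
#' @param m_rate immune motility attempt rate.
#' @param tau_lys debris persistence before lysis, hours.
#' @param dt time step, hours.
#' @param chemokine named list of [chemokine_fields()] parameters.
#' @param trafficking a [trafficking_params()] object.
#' @param debug if TRUE, assert the single-occupancy invariant every step.
#' @return A `sim_params` list.
#' @export
simulation_params <- function(k_pro = 0.03, k_apt = 0.0021, k_dge = 0,
                              k_kill = 0.1, k_sup = 0.05, theta = 1,
                              c_act = 0.05, chi = 30, m_rate = 4,
                              tau_lys = 12, dt = 1,
                              chemokine = list(), trafficking = trafficking_params(),
                              debug = FALSE) {
  stopifnot(k_pro >= 0, k_apt >= 0, k_dge >= 0, k_dge <= 1, k_kill >= 0,
            k_sup >= 0, theta > 0, chi >= 0, m_rate >= 0, tau_lys >= 0, dt > 0)
  structure(list(
    k_pro = k_pro, k_apt = k_apt, k_dge = k_dge, k_kill = k_kill,
    k_sup = k_sup, theta = theta, c_act = c_act, chi = chi, m_rate = m_rate,
    tau_lys = tau_lys, dt = dt, chemokine = chemokine,
    trafficking = trafficking, debug = debug
  ), class = "sim_params")
}

#' Per-step event probability from a contact-proportional hazard
#'
#' `1 - exp(-rate * n_contacts * dt)`: the hazard `-log(1 - p)/dt` is exactly
#' linear in the number of contacts. Used for contact killing and
#' suppression; with `n_contacts = 1` for intrinsic rates.
#'
#' @param rate rate per hour (>= 0).
#' @param n_contacts number of contributing contacts (>= 0).
#' @param dt time step, hours (> 0).
#' @return probability in `[0, 1]`.
#' @export
event_probability <- function(rate, n_contacts = 1, dt = 1) {
  stopifnot(all(rate >= 0), all(n_contacts >= 0), all(dt > 0))
  1 - exp(-rate * n_contacts * dt)
}

# --- simulation state --------------------------------------------------------

grow_cells <- function(sim, need) {
  cap <- length(sim$type)
  if (sim$n_slots + need <= cap) return(invisible(sim))
  newcap <- max(cap * 2L, cap + need)
  length(sim$node) <- newcap
  length(sim$type) <- newcap
  length(sim$state) <- newcap
  length(sim$dying_since) <- newcap
  length(sim$alive) <- newcap
  sim$alive[(cap + 1L):newcap] <- FALSE
  invisible(sim)
}

add_cell <- function(sim, node, type, state) {
  if (length(sim$free_slots)) {
    id <- sim$free_slots[length(sim$free_slots)]
    sim$free_slots <- sim$free_slots[-length(sim$free_slots)]
  } else {
    grow_cells(sim, 1L)
    sim$n_slots <- sim$n_slots + 1L
    id <- sim$n_slots
  }
  sim$node[id] <- node
  sim$type[id] <- type
  sim$state[id] <- state
  sim$dying_since[id] <- NA_real_
  sim$alive[id] <- TRUE
  sim$occ[node] <- id
  id
}

remove_cell <- function(sim, id) {
  sim$occ[sim$node[id]] <- 0L
  sim$alive[id] <- FALSE
  sim$free_slots <- c(sim$free_slots, id)
  invisible(sim)
}

#' Initialize a simulation state
#'
#' Every epithelial-compartment node starts occupied by a NORMAL epithelial
#' cell of the matching type; the immune compartment starts empty and fills
#' through trafficking (relaxation time ~ 1/lam_out).
#'
#' @param domain a [tdlu_domain].
#' @param profile a [hormone_profile].
#' @param params a [simulation_params()].
#' @return A `tdlu_sim` environment.
#' @export
new_simulation <- function(domain, profile, params = simulation_params()) {
  n <- domain$width * domain$height
  sim <- new.env(parent = emptyenv())
  class(sim) <- "tdlu_sim"
  sim$domain <- domain
  sim$profile <- profile
  sim$params <- params
  sim$n_nodes <- n
  sim$t_h <- 0
  sim$fields <- do.call(chemokine_fields, c(list(domain), params$chemokine))
  sim$stromal <- stromal_nodes(domain)

  comp <- as.integer(domain$compartment)
  epi_nodes <- which(comp == COMPARTMENTS[["LUMINAL_EPITHELIUM"]] |
                       comp == COMPARTMENTS[["MYOEPITHELIUM"]])
  cap <- length(epi_nodes) + 512L
  sim$node <- integer(cap)
  sim$type <- integer(cap)
  sim$state <- integer(cap)
  sim$dying_since <- rep(NA_real_, cap)
  sim$alive <- logical(cap)
  sim$occ <- integer(n + 1L)
  sim$occ[n + 1L] <- -1L  # sentinel: never free
  sim$n_slots <- 0L
  sim$free_slots <- integer()
  sim$scratch <- numeric(n + 1L)

  k <- length(epi_nodes)
  ids <- seq_len(k)
  sim$n_slots <- k
  sim$node[ids] <- epi_nodes
  sim$type[ids] <- ifelse(comp[epi_nodes] == COMPARTMENTS[["LUMINAL_EPITHELIUM"]],
                          CELL_TYPES[["EPI_LUMINAL"]], CELL_TYPES[["EPI_MYO"]])
  sim$state[ids] <- EPI_STATES[["NORMAL"]]
  sim$alive[ids] <- TRUE
  sim$occ[epi_nodes] <- ids
  sim$epi_ids <- ids
  sim$dying_ids <- integer()
  sim$imm_ids <- integer()
  sim$last <- list(n_div_trig = 0L, n_div_done = 0L, n_apt = 0L,
                   n_killed = 0L, n_suppressed = 0L, n_lysed = 0L,
                   n_in = 0L, n_out = 0L)
  sim
}

#' @export
print.tdlu_sim <- function(x, ...) {
  cat("TDLU simulation at t = ", x$t_h, " h\n", sep = "")
  cat("  epithelial: ", length(x$epi_ids),
      " (damaged ", sum(x$state[x$epi_ids] == EPI_STATES[["DAMAGED"]]),
      "), dying: ", length(x$dying_ids),
      ", immune: ", length(x$imm_ids), "\n", sep = "")
  invisible(x)
}

# --- single-cell operations (also used directly by the step loop for the
# --- sparse event sets; exported for inspection and unit testing) -----------

#' Attempt a division for one epithelial cell
#'
#' With probability `1 - exp(-rate_pro * dt)` the cell commits to division
#' (the Ki-67 analogue counted by the PI read-out); the daughter is placed on
#' a uniformly chosen free epithelial-compartment Moore neighbor if one
#' exists, otherwise the division is blocked. The daughter of a NORMAL parent
#' is DAMAGED with probability `k_dge`; the daughter of a DAMAGED parent is
#' always DAMAGED.
#'
#' @param sim a `tdlu_sim`.
#' @param id cell id (epithelial, not DYING).
#' @param rate_pro hormone-modulated division rate at the current time.
#' @return list `(triggered, placed, daughter_id)`.
#' @export
attempt_division <- function(sim, id, rate_pro) {
  stopifnot(is_epithelial(sim$type[id]),
            sim$state[id] != EPI_STATES[["DYING"]])
  if (stats::runif(1) >= event_probability(rate_pro, 1, sim$params$dt)) {
    return(list(triggered = FALSE, placed = FALSE, daughter_id = NA_integer_))
  }
  d_id <- place_daughter(sim, id)
  list(triggered = TRUE, placed = !is.na(d_id), daughter_id = d_id)
}

place_daughter <- function(sim, id) {
  nb <- sim$domain$nb_moore[sim$node[id], ]
  free <- nb[sim$occ[nb] == 0L &
               (sim$domain$comp_v[nb] == COMPARTMENTS[["LUMINAL_EPITHELIUM"]] |
                  sim$domain$comp_v[nb] == COMPARTMENTS[["MYOEPITHELIUM"]])]
  if (!length(free)) return(NA_integer_)
  tgt <- if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
  damaged <- sim$state[id] == EPI_STATES[["DAMAGED"]] ||
    stats::runif(1) < sim$params$k_dge
  d_id <- add_cell(sim, tgt, sim$type[id],
                   if (damaged) EPI_STATES[["DAMAGED"]] else EPI_STATES[["NORMAL"]])
  sim$epi_ids <- c(sim$epi_ids, d_id)
  d_id
}

#' Attempt apoptosis for one NORMAL epithelial cell
#'
#' DAMAGED cells never die by apoptosis (no-op). Apoptosis needs no free
#' neighbor; it is the only process available to crowded cells.
#'
#' @param sim a `tdlu_sim`.
#' @param id cell id.
#' @param rate_apt hormone-modulated apoptosis rate.
#' @return TRUE if the cell entered the DYING state.
#' @export
attempt_apoptosis <- function(sim, id, rate_apt) {
  if (sim$state[id] != EPI_STATES[["NORMAL"]]) return(FALSE)
  if (stats::runif(1) >= event_probability(rate_apt, 1, sim$params$dt)) {
    return(FALSE)
  }
  enter_dying(sim, id)
  TRUE
}

enter_dying <- function(sim, id) {
  sim$state[id] <- EPI_STATES[["DYING"]]
  sim$dying_since[id] <- sim$t_h
  sim$epi_ids <- sim$epi_ids[sim$epi_ids != id]
  sim$dying_ids <- c(sim$dying_ids, id)
  invisible(sim)
}

count_adjacent <- function(sim, node, ids) {
  if (!length(ids)) return(0L)
  sum(sim$domain$nb_moore[node, ] %in% sim$node[ids])
}

#' Contact-killing checkpoint for one DAMAGED epithelial cell
#'
#' The target enters DYING with probability
#' `event_probability(k_kill, n_active_effectors, dt)` counted over the Moore
#' neighborhood. Inactive effectors do not contribute.
#'
#' @param sim a `tdlu_sim`.
#' @param id DAMAGED cell id.
#' @return TRUE if the target entered DYING.
#' @export
kill_check <- function(sim, id) {
  stopifnot(sim$state[id] == EPI_STATES[["DAMAGED"]])
  eff_act <- sim$imm_ids[sim$type[sim$imm_ids] == CELL_TYPES[["EFFECTOR"]] &
                           sim$state[sim$imm_ids] == IMM_STATES[["ACTIVE"]]]
  k <- count_adjacent(sim, sim$node[id], eff_act)
  if (stats::runif(1) < event_probability(sim$params$k_kill, k, sim$params$dt)) {
    enter_dying(sim, id)
    return(TRUE)
  }
  FALSE
}

#' Suppression checkpoint for one ACTIVE effector
#'
#' The effector becomes PERM_INACTIVE (irreversibly) with probability
#' `event_probability(k_sup, n_active_regulatory, dt)`.
#'
#' @param sim a `tdlu_sim`.
#' @param id ACTIVE effector id.
#' @return TRUE if the effector was permanently inactivated.
#' @export
suppression_check <- function(sim, id) {
  stopifnot(sim$type[id] == CELL_TYPES[["EFFECTOR"]],
            sim$state[id] == IMM_STATES[["ACTIVE"]])
  reg_act <- sim$imm_ids[sim$type[sim$imm_ids] == CELL_TYPES[["REGULATORY"]] &
                           sim$state[sim$imm_ids] == IMM_STATES[["ACTIVE"]]]
  k <- count_adjacent(sim, sim$node[id], reg_act)
  if (stats::runif(1) < event_probability(sim$params$k_sup, k, sim$params$dt)) {
    sim$state[id] <- IMM_STATES[["PERM_INACTIVE"]]
    return(TRUE)
  }
  FALSE
}

#' Activation checkpoint for one immune cell
#'
#' ACTIVE iff the damaged-cell chemokine at the cell's node is at least
#' `c_act` (threshold inclusive); PERM_INACTIVE cells never change.
#'
#' @param sim a `tdlu_sim`.
#' @param id immune cell id.
#' @return the updated immune state code.
#' @export
activation_update <- function(sim, id) {
  if (sim$state[id] == IMM_STATES[["PERM_INACTIVE"]]) {
    return(sim$state[id])
  }
  sim$state[id] <- if (sim$fields$c_dam[sim$node[id]] >= sim$params$c_act) {
    IMM_STATES[["ACTIVE"]]
  } else {
    IMM_STATES[["INACTIVE"]]
  }
  sim$state[id]
}

#' Chemotactic step weights for one immune cell
#'
#' Admissible targets are free, non-lumen Moore neighbors. Weights are
#' `exp(chi * dC)` where `dC` is the local difference of `C_dam + C_dying`
#' for effectors and of `C_dam` for regulatory cells (softmax over
#' neighbors; numerically stabilized).
#'
#' @param sim a `tdlu_sim`.
#' @param id immune cell id.
#' @return list `(targets, weights)`; zero-length if no admissible neighbor.
#' @export
move_weights <- function(sim, id) {
  node <- sim$node[id]
  nb <- sim$domain$nb_moore[node, ]
  ok <- sim$occ[nb] == 0L &
    sim$domain$comp_v[nb] != COMPARTMENTS[["LUMEN"]]
  nb <- nb[ok]
  if (!length(nb)) return(list(targets = integer(), weights = numeric()))
  if (sim$type[id] == CELL_TYPES[["EFFECTOR"]]) {
    dC <- (sim$fields$c_dam[nb] + sim$fields$c_dying[nb]) -
      (sim$fields$c_dam[node] + sim$fields$c_dying[node])
  } else {
    dC <- sim$fields$c_dam[nb] - sim$fields$c_dam[node]
  }
  w <- exp(sim$params$chi * (dC - max(dC)))
  list(targets = nb, weights = w / sum(w))
}

#' Motility attempt for one immune cell
#'
#' With probability `1 - exp(-m_rate * dt)` the cell steps to one admissible
#' neighbor drawn with the chemotactic weights of [move_weights()]; it stays
#' put if no admissible neighbor exists.
#'
#' @param sim a `tdlu_sim`.
#' @param id immune cell id.
#' @return the (possibly unchanged) node of the cell.
#' @export
move_immune <- function(sim, id) {
  if (stats::runif(1) >= event_probability(sim$params$m_rate, 1, sim$params$dt)) {
    return(sim$node[id])
  }
  mw <- move_weights(sim, id)
  if (!length(mw$targets)) return(sim$node[id])
  cw <- cumsum(mw$weights)
  tgt <- mw$targets[findInterval(stats::runif(1), cw, left.open = TRUE) + 1L]
  sim$occ[sim$node[id]] <- 0L
  sim$occ[tgt] <- id
  sim$node[id] <- tgt
  tgt
}

#' Lysis: remove expired dying cells
#'
#' Deletes every DYING cell with `now - dying_since >= tau_lys`, freeing its
#' node; while DYING a cell remains a source of the dying-cell chemokine.
#'
#' @param sim a `tdlu_sim`.
#' @param now current time in hours (defaults to the simulation clock).
#' @param tau_lys debris persistence (defaults to the configured value).
#' @return number of removed cells.
#' @export
lysis_update <- function(sim, now = sim$t_h, tau_lys = sim$params$tau_lys) {
  dying <- sim$dying_ids
  expired <- dying[now - sim$dying_since[dying] >= tau_lys - 1e-9]
  for (id in expired) remove_cell(sim, id)
  sim$dying_ids <- setdiff(dying, expired)
  length(expired)
}

# --- full step ---------------------------------------------------------------

#' Advance the simulation by one time step
#'
#' Executes the checkpoint phase (activation, killing, suppression, lysis) on
#' the step-start state, then the action phase over a fresh random
#' permutation of candidate cells, then the chemokine field update and
#' trafficking. Event counts of the step are stored in `sim$last`.
#'
#' @param sim a `tdlu_sim`.
#' @return the simulation, invisibly.
#' @export
step_simulation <- function(sim) {
  p <- sim$params
  dt <- p$dt
  rates <- hormone_rates(sim$profile, sim$t_h, p$k_pro, p$k_apt, p$theta)
  now <- sim$t_h
  nbm <- sim$domain$nb_moore
  cv <- sim$domain$comp_v
  cdam <- sim$fields$c_dam
  counts <- list(n_div_trig = 0L, n_div_done = 0L, n_apt = 0L, n_killed = 0L,
                 n_suppressed = 0L, n_lysed = 0L, n_in = 0L, n_out = 0L)

  # local working copies of the cell table (written back once per step)
  node <- sim$node
  type <- sim$type
  state <- sim$state
  dying_since <- sim$dying_since
  alive <- sim$alive
  occ <- sim$occ
  n_slots <- sim$n_slots
  free_slots <- sim$free_slots
  epi <- sim$epi_ids
  dying <- sim$dying_ids
  imm <- sim$imm_ids
  LUM <- COMPARTMENTS[["LUMEN"]]
  EPI_L <- COMPARTMENTS[["LUMINAL_EPITHELIUM"]]
  EPI_M <- COMPARTMENTS[["MYOEPITHELIUM"]]
  DAMAGED <- EPI_STATES[["DAMAGED"]]
  DYING <- EPI_STATES[["DYING"]]
  NORMAL <- EPI_STATES[["NORMAL"]]
  ACT <- IMM_STATES[["ACTIVE"]]
  INACT <- IMM_STATES[["INACTIVE"]]
  PERM <- IMM_STATES[["PERM_INACTIVE"]]

  ## checkpoint phase ---------------------------------------------------------
  if (length(imm)) {
    st <- state[imm]
    on <- cdam[node[imm]] >= p$c_act
    state[imm] <- ifelse(st == PERM, PERM, ifelse(on, ACT, INACT))
  }

  dmg <- epi[state[epi] == DAMAGED]
  if (length(dmg) && p$k_kill > 0 && length(imm)) {
    eff_act <- imm[type[imm] == CELL_TYPES[["EFFECTOR"]] & state[imm] == ACT]
    if (length(eff_act)) {
      ind <- sim$scratch
      ind[node[eff_act]] <- 1
      cnt <- .rowSums(ind[nbm[node[dmg], , drop = FALSE]], length(dmg), 8L)
      ind[node[eff_act]] <- 0
      sim$scratch <- ind
      hit <- stats::runif(length(dmg)) < 1 - exp(-p$k_kill * cnt * dt)
      killed <- dmg[hit]
      if (length(killed)) {
        state[killed] <- DYING
        dying_since[killed] <- now
        epi <- epi[!epi %in% killed]
        dying <- c(dying, killed)
      }
      counts$n_killed <- length(killed)
    }
  }

  if (length(imm) && p$k_sup > 0) {
    eff_act <- imm[type[imm] == CELL_TYPES[["EFFECTOR"]] & state[imm] == ACT]
    reg_act <- imm[type[imm] == CELL_TYPES[["REGULATORY"]] & state[imm] == ACT]
    if (length(eff_act) && length(reg_act)) {
      ind <- sim$scratch
      ind[node[reg_act]] <- 1
      cnt <- .rowSums(ind[nbm[node[eff_act], , drop = FALSE]],
                      length(eff_act), 8L)
      ind[node[reg_act]] <- 0
      sim$scratch <- ind
      hit <- stats::runif(length(eff_act)) < 1 - exp(-p$k_sup * cnt * dt)
      state[eff_act[hit]] <- PERM
      counts$n_suppressed <- sum(hit)
    }
  }

  expired <- dying[now - dying_since[dying] >= p$tau_lys - 1e-9]
  if (length(expired)) {
    occ[node[expired]] <- 0L
    alive[expired] <- FALSE
    free_slots <- c(free_slots, expired)
    dying <- dying[!dying %in% expired]
  }
  counts$n_lysed <- length(expired)

  ## action phase -------------------------------------------------------------
  p_div <- 1 - exp(-rates$rate_pro * dt)
  p_apt <- 1 - exp(-rates$rate_apt * dt)
  div_trig <- stats::runif(length(epi)) < p_div
  apt_trig <- state[epi] == NORMAL & stats::runif(length(epi)) < p_apt
  any_t <- div_trig | apt_trig
  epi_actors <- epi[any_t]
  div_t <- div_trig[any_t]
  apt_t <- apt_trig[any_t]

  mov <- if (length(imm)) {
    imm[stats::runif(length(imm)) < 1 - exp(-p$m_rate * dt)]
  } else integer()

  new_epi <- integer()
  n_act <- length(epi_actors) + length(mov)
  if (n_act) {
    cc <- cdam + sim$fields$c_dying  # effector chemotaxis field
    k_dge <- p$k_dge
    chi <- p$chi
    ord <- sample.int(n_act)
    n_ea <- length(epi_actors)
    actor <- c(epi_actors, mov)
    div_first <- stats::runif(n_ea) < 0.5
    cap <- length(type)
    for (j in ord) {
      id <- actor[j]
      if (j <= n_ea) {
        do_div <- FALSE
        do_apt <- FALSE
        if (div_first[j]) {
          if (div_t[j]) do_div <- TRUE
          if (apt_t[j]) do_apt <- TRUE
        } else if (apt_t[j]) {
          do_apt <- TRUE
        } else if (div_t[j]) {
          do_div <- TRUE
        }
        placed <- FALSE
        if (do_div) {
          counts$n_div_trig <- counts$n_div_trig + 1L
          nb <- nbm[node[id], ]
          cnb <- cv[nb]
          free <- nb[occ[nb] == 0L & (cnb == EPI_L | cnb == EPI_M)]
          if (length(free)) {
            tgt <- if (length(free) == 1L) free else
              free[sample.int(length(free), 1L)]
            damaged <- state[id] == DAMAGED || stats::runif(1) < k_dge
            if (length(free_slots)) {
              slot <- free_slots[length(free_slots)]
              free_slots <- free_slots[-length(free_slots)]
            } else {
              n_slots <- n_slots + 1L
              slot <- n_slots
              if (slot > cap) {
                newcap <- cap * 2L
                length(node) <- newcap
                length(type) <- newcap
                length(state) <- newcap
                length(dying_since) <- newcap
                length(alive) <- newcap
                alive[(cap + 1L):newcap] <- FALSE
                cap <- newcap
              }
            }
            node[slot] <- tgt
            type[slot] <- type[id]
            state[slot] <- if (damaged) DAMAGED else NORMAL
            dying_since[slot] <- NA_real_
            alive[slot] <- TRUE
            occ[tgt] <- slot
            new_epi <- c(new_epi, slot)
            counts$n_div_done <- counts$n_div_done + 1L
            placed <- TRUE
          }
        }
        if (do_apt && !placed && state[id] == NORMAL) {
          state[id] <- DYING
          dying_since[id] <- now
          dying <- c(dying, id)
          counts$n_apt <- counts$n_apt + 1L
        }
      } else {
        from <- node[id]
        nb <- nbm[from, ]
        ok <- occ[nb] == 0L & cv[nb] != LUM
        if (any(ok)) {
          nbo <- nb[ok]
          if (length(nbo) == 1L) {
            tgt <- nbo
          } else {
            f <- if (type[id] == CELL_TYPES[["EFFECTOR"]]) cc else cdam
            dC <- f[nbo] - f[from]
            w <- exp(chi * (dC - max(dC)))
            cw <- cumsum(w)
            tgt <- nbo[which.max(cw >= stats::runif(1) * cw[length(w)])]
          }
          occ[from] <- 0L
          occ[tgt] <- id
          node[id] <- tgt
        }
      }
    }
  }
  if (length(new_epi)) epi <- c(epi, new_epi)
  if (counts$n_apt > 0L) epi <- epi[state[epi] != DYING]

  ## write back ---------------------------------------------------------------
  sim$node <- node
  sim$type <- type
  sim$state <- state
  sim$dying_since <- dying_since
  sim$alive <- alive
  sim$occ <- occ
  sim$n_slots <- n_slots
  sim$free_slots <- free_slots
  sim$epi_ids <- epi
  sim$dying_ids <- dying

  ## chemokine fields ---------------------------------------------------------
  src_dam <- node[epi[state[epi] == DAMAGED]]
  src_dying <- node[dying]
  sim$fields <- advance_fields(sim$fields, sim$domain, src_dam, src_dying, dt)

  ## trafficking --------------------------------------------------------------
  tr <- apply_trafficking(sim)
  counts$n_in <- tr$n_in
  counts$n_out <- tr$n_out

  sim$t_h <- sim$t_h + dt
  sim$last <- counts

  if (isTRUE(p$debug)) {
    live <- which(sim$alive[seq_len(sim$n_slots)])
    stopifnot(!anyDuplicated(sim$node[live]),
              all(sim$occ[sim$node[live]] == live))
  }
  invisible(sim)
}

# --- run loop ----------------------------------------------------------------

#' Run a simulation for a number of menstrual cycles
#'
#' @param domain a [tdlu_domain].
#' @param profile a [hormone_profile].
#' @param params a [simulation_params()].
#' @param n_cycles number of cycles to simulate.
#' @param seed optional integer seed (set before state construction).
#' @param snapshot_days days-of-cycle at which to record immune cell point
#'   snapshots (e.g. `c(5, 14, 25)`); `NULL` disables snapshots.
#' @param snapshot_cycles cycles (1-based) at which snapshots are taken;
#'   default all cycles.
#' @return list with `series` (one row per step: counts, relative numbers,
#'   PI/AI samples), `snapshots` (list of data frames) and the final `sim`.
#' @export
run_simulation <- function(domain, profile, params = simulation_params(),
                           n_cycles = 12, seed = NULL, snapshot_days = NULL,
                           snapshot_cycles = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- new_simulation(domain, profile, params)
  cl_h <- cycle_length(profile) * 24
  n_steps <- as.integer(round(n_cycles * cl_h / params$dt))
  cols <- c("t_h", "n_epi", "n_damaged", "n_dying",
            "n_eff_active", "n_eff_inactive", "n_eff_perm",
            "n_reg_active", "n_reg_inactive",
            "rel_eff", "rel_reg", "rel_damaged",
            "pi_sample", "ai_sample", "n_div_done")
  out <- matrix(NA_real_, n_steps, length(cols), dimnames = list(NULL, cols))
  snaps <- list()

  for (i in seq_len(n_steps)) {
    step_simulation(sim)
    epi <- sim$epi_ids
    imm <- sim$imm_ids
    n_epi <- length(epi)
    ty <- sim$type[imm]
    st <- sim$state[imm]
    is_eff <- ty == CELL_TYPES[["EFFECTOR"]]
    n_eff <- sum(is_eff)
    n_reg <- length(imm) - n_eff
    out[i, ] <- c(
      sim$t_h, n_epi,
      sum(sim$state[epi] == EPI_STATES[["DAMAGED"]]),
      length(sim$dying_ids),
      sum(is_eff & st == IMM_STATES[["ACTIVE"]]),
      sum(is_eff & st == IMM_STATES[["INACTIVE"]]),
      sum(is_eff & st == IMM_STATES[["PERM_INACTIVE"]]),
      sum(!is_eff & st == IMM_STATES[["ACTIVE"]]),
      sum(!is_eff & st != IMM_STATES[["ACTIVE"]]),
      n_eff / n_epi, n_reg / n_epi,
      sum(sim$state[epi] == EPI_STATES[["DAMAGED"]]) / n_epi,
      1000 * sim$last$n_div_trig / (n_epi * params$dt),
      1000 * sim$last$n_apt / (n_epi * params$dt),
      sim$last$n_div_done
    )
    if (!is.null(snapshot_days)) {
      day <- (sim$t_h / 24) %% cycle_length(profile)
      cyc <- floor((sim$t_h / 24) / cycle_length(profile)) + 1
      hit <- any(abs(day - snapshot_days) < params$dt / 48)
      in_cycle <- is.null(snapshot_cycles) || cyc %in% snapshot_cycles
      if (hit && in_cycle && length(imm)) {
        xy <- idx_to_xy(sim$node[imm], domain$width)
        snaps[[length(snaps) + 1L]] <- data.frame(
          t_h = sim$t_h, cycle = cyc, day = round(day, 6),
          x = xy[, 1], y = xy[, 2],
          cell_type = names(CELL_TYPES)[ty],
          state = names(IMM_STATES)[st]
        )
      }
    }
  }
  list(series = as.data.frame(out), snapshots = snaps, sim = sim)
}

#' Snapshot of all live cells as a data frame
#'
#' Columns `t_h, cell_id, x, y, cell_type, state` (states labelled by type).
#' @param sim a `tdlu_sim`.
#' @return data frame.
#' @export
snapshot_cells <- function(sim) {
  live <- which(sim$alive[seq_len(sim$n_slots)])
  xy <- idx_to_xy(sim$node[live], sim$domain$width)
  ty <- sim$type[live]
  st <- ifelse(is_epithelial(ty), names(EPI_STATES)[sim$state[live]],
               names(IMM_STATES)[sim$state[live]])
  data.frame(t_h = sim$t_h, cell_id = live, x = xy[, 1], y = xy[, 2],
             cell_type = names(CELL_TYPES)[ty], state = st)
}
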