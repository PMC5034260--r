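# helper: fresh simulation on the small two-acinus domain
mk_sim <- function(params = quick_params(), seed = 1,
                   domain = small_domain()) {
  set.seed(seed)
  new_simulation(domain, default_profile(), params)
}

# helper: put an immune cell on a given node
spawn_immune <- function(sim, node, type = CELL_TYPES[["EFFECTOR"]],
                         state = IMM_STATES[["INACTIVE"]]) {
  id <- tdlusim:::add_cell(sim, node, type, state)
  sim$imm_ids <- c(sim$imm_ids, id)
  id
}

test_that("event probabilities follow the contact-proportional hazard exactly", {
  expect_equal(event_probability(0.5, 0, 1), 0)
  expect_equal(event_probability(0.05, 1, 1), 1 - exp(-0.05))
  expect_equal(event_probability(0.10, 3, 1), 1 - exp(-0.3))
  expect_equal(event_probability(0.05, 2, 1), 1 - exp(-0.1))
  # hazard -log(1-p)/dt is exactly linear in the contact count
  for (n in 0:8) {
    p <- event_probability(0.07, n, 0.5)
    expect_equal(-log(1 - p) / 0.5, 0.07 * n, tolerance = 1e-12)
  }
})

test_that("division respects crowding, lineage and the damage probability", {
  dom <- small_domain()
  # fully crowded epithelium: high rate but no free node -> never places
  sim <- mk_sim(domain = dom)
  id <- sim$epi_ids[10]
  res <- attempt_division(sim, id, rate_pro = 100)
  expect_true(res$triggered)
  expect_false(res$placed)
  # free a neighbor: daughter of a NORMAL parent with k_dge = 0 is NORMAL
  sim <- mk_sim(seed = 2, domain = dom)
  id <- sim$epi_ids[1]
  nb_epi <- node_neighbors(dom, sim$node[id])
  nb_epi <- nb_epi[dom$comp_v[nb_epi] %in%
                     COMPARTMENTS[c("LUMINAL_EPITHELIUM", "MYOEPITHELIUM")]]
  victim <- sim$occ[nb_epi[1]]
  tdlusim:::remove_cell(sim, victim)
  sim$epi_ids <- setdiff(sim$epi_ids, victim)
  res <- attempt_division(sim, id, rate_pro = 100)
  expect_true(res$placed)
  expect_equal(sim$state[res$daughter_id], EPI_STATES[["NORMAL"]])
  # k_dge = 1: daughter of a NORMAL parent is always DAMAGED
  sim <- mk_sim(seed = 3, domain = dom)
  sim$params$k_dge <- 1
  id <- sim$epi_ids[1]
  victim <- sim$occ[nb_epi[1]]
  tdlusim:::remove_cell(sim, victim)
  sim$epi_ids <- setdiff(sim$epi_ids, victim)
  res <- attempt_division(sim, id, rate_pro = 100)
  expect_equal(sim$state[res$daughter_id], EPI_STATES[["DAMAGED"]])
  # DAMAGED parent begets DAMAGED daughter even with k_dge = 0
  sim <- mk_sim(seed = 4, domain = dom)
  id <- sim$epi_ids[1]
  sim$state[id] <- EPI_STATES[["DAMAGED"]]
  victim <- sim$occ[nb_epi[1]]
  tdlusim:::remove_cell(sim, victim)
  sim$epi_ids <- setdiff(sim$epi_ids, victim)
  res <- attempt_division(sim, id, rate_pro = 100)
  expect_equal(sim$state[res$daughter_id], EPI_STATES[["DAMAGED"]])
})

test_that("apoptosis spares damaged cells and kill/suppression need contacts", {
  sim <- mk_sim()
  id <- sim$epi_ids[1]
  sim$state[id] <- EPI_STATES[["DAMAGED"]]
  expect_false(attempt_apoptosis(sim, id, rate_apt = 1e6))
  expect_equal(sim$state[id], EPI_STATES[["DAMAGED"]])
  id2 <- sim$epi_ids[2]
  expect_false(attempt_apoptosis(sim, id2, rate_apt = 0))
  expect_true(attempt_apoptosis(sim, id2, rate_apt = 1e6))
  expect_equal(sim$state[id2], EPI_STATES[["DYING"]])

  # kill: no adjacent active effector -> no-op even at huge k_kill
  sim <- mk_sim(seed = 5)
  sim$params$k_kill <- 1e6
  dmg <- sim$epi_ids[1]
  sim$state[dmg] <- EPI_STATES[["DAMAGED"]]
  expect_false(kill_check(sim, dmg))
  # an INACTIVE adjacent effector contributes nothing
  st_nb <- node_neighbors(sim$domain, sim$node[dmg])
  free_nb <- st_nb[sim$occ[st_nb] == 0L &
                     sim$domain$comp_v[st_nb] != COMPARTMENTS[["LUMEN"]]]
  eid <- spawn_immune(sim, free_nb[1], state = IMM_STATES[["INACTIVE"]])
  expect_false(kill_check(sim, dmg))
  # an ACTIVE one kills with probability -> 1
  sim$state[eid] <- IMM_STATES[["ACTIVE"]]
  expect_true(kill_check(sim, dmg))
  expect_equal(sim$state[dmg], EPI_STATES[["DYING"]])

  # suppression: requires adjacent ACTIVE regulatory cells
  sim <- mk_sim(seed = 6)
  sim$params$k_sup <- 1e6
  node <- stromal_nodes(sim$domain)[3]
  eff <- spawn_immune(sim, node, state = IMM_STATES[["ACTIVE"]])
  expect_false(suppression_check(sim, eff))
  nb <- node_neighbors(sim$domain, node)
  nb <- nb[sim$occ[nb] == 0L &
             sim$domain$comp_v[nb] != COMPARTMENTS[["LUMEN"]]]
  reg <- spawn_immune(sim, nb[1], type = CELL_TYPES[["REGULATORY"]],
                      state = IMM_STATES[["ACTIVE"]])
  expect_true(suppression_check(sim, eff))
  expect_equal(sim$state[eff], IMM_STATES[["PERM_INACTIVE"]])
  # permanent inactivation is irreversible under any chemokine exposure
  sim$fields$c_dam[sim$node[eff]] <- 1e3
  activation_update(sim, eff)
  expect_equal(sim$state[eff], IMM_STATES[["PERM_INACTIVE"]])
})

test_that("activation threshold is inclusive and deterministic", {
  sim <- mk_sim(seed = 7)
  node <- stromal_nodes(sim$domain)[10]
  id <- spawn_immune(sim, node)
  sim$fields$c_dam[node] <- 0
  expect_equal(activation_update(sim, id), IMM_STATES[["INACTIVE"]])
  sim$fields$c_dam[node] <- sim$params$c_act  # exactly at threshold
  expect_equal(activation_update(sim, id), IMM_STATES[["ACTIVE"]])
  sim$fields$c_dam[node] <- sim$params$c_act - 1e-9
  expect_equal(activation_update(sim, id), IMM_STATES[["INACTIVE"]])
})

test_that("immune movement avoids lumina, is uniform on flat fields and
           follows softmax weights on gradients", {
  sim <- mk_sim(seed = 8)
  sim$params$m_rate <- 1e6  # always move
  # vacate a luminal-epithelium node (lumen-adjacent) and park an effector on
  # it: its admissible moves must never enter the lumen
  lum_epi <- which(as.integer(sim$domain$compartment) ==
                     COMPARTMENTS[["LUMINAL_EPITHELIUM"]])
  vac <- lum_epi[1]
  vac2 <- intersect(node_neighbors(sim$domain, vac), lum_epi)[1]
  for (victim in sim$occ[c(vac, vac2)]) {
    tdlusim:::remove_cell(sim, victim)
    sim$epi_ids <- setdiff(sim$epi_ids, victim)
  }
  id <- spawn_immune(sim, vac)
  expect_true(any(sim$domain$comp_v[node_neighbors(sim$domain, vac)] ==
                    COMPARTMENTS[["LUMEN"]]))
  for (i in 1:60) {
    move_immune(sim, id)
    expect_true(sim$domain$comp_v[sim$node[id]] != COMPARTMENTS[["LUMEN"]])
  }
  # flat field: empirical step distribution uniform over admissible targets
  sim <- mk_sim(seed = 9)
  sim$params$m_rate <- 1e6
  node <- stromal_nodes(sim$domain)[35]
  id <- spawn_immune(sim, node)
  mw <- move_weights(sim, id)
  k <- length(mw$targets)
  expect_true(k >= 4)
  expect_equal(mw$weights, rep(1 / k, k))
  counts <- integer(k)
  set.seed(11)
  for (i in 1:5000) {
    tgt <- move_immune(sim, id)
    counts[match(tgt, mw$targets)] <- counts[match(tgt, mw$targets)] + 1L
    sim$occ[tgt] <- 0L  # reset position
    sim$occ[node] <- id
    sim$node[id] <- node
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  # gradient: weights match a brute-force softmax and the uphill neighbor
  # dominates at large chi
  sim$fields$c_dam[] <- matrix(0.05 * seq_len(sim$domain$width),
                               sim$domain$width, sim$domain$height)
  sim$params$chi <- 300  # steep enough that lateral steps carry ~e^-15
  mw <- move_weights(sim, id)
  dC <- sim$fields$c_dam[mw$targets] - sim$fields$c_dam[node]
  w_ref <- exp(300 * (dC - max(dC)))
  expect_equal(mw$weights, w_ref / sum(w_ref), tolerance = 1e-12)
  xy <- tdlusim:::idx_to_xy(c(node, mw$targets), sim$domain$width)
  uphill <- mw$targets[xy[-1, 1] > xy[1, 1]]
  expect_gt(sum(mw$weights[mw$targets %in% uphill]), 0.999)
})

test_that("lysis removes debris exactly at the persistence time", {
  sim <- mk_sim(seed = 10)
  id <- sim$epi_ids[1]
  node <- sim$node[id]
  sim$t_h <- 5
  tdlusim:::enter_dying(sim, id)
  sim$params$tau_lys <- 12
  for (t in 6:16) {
    sim$t_h <- t
    expect_equal(lysis_update(sim), 0L)
  }
  sim$t_h <- 17
  expect_equal(lysis_update(sim), 1L)
  expect_equal(sim$occ[node], 0L)  # node freed for later division
  # tau_lys = 0: removal in the same step the cell enters DYING
  id2 <- sim$epi_ids[1]
  tdlusim:::enter_dying(sim, id2)
  expect_equal(lysis_update(sim, tau_lys = 0), 1L)
})

test_that("steps are deterministic under a seed and keep single occupancy", {
  dom <- small_domain()
  p <- default_profile()
  pr <- quick_params(k_dge = 0.1, k_kill = 0.05)
  a <- run_simulation(dom, p, pr, n_cycles = 1, seed = 123)
  b <- run_simulation(dom, p, pr, n_cycles = 1, seed = 123)
  expect_identical(a$series, b$series)  # debug = TRUE asserts occupancy
  expect_true(all(a$series$n_epi > 0))
})

test_that("damaged cells only accumulate when killing is disabled", {
  dom <- small_domain()
  pr <- quick_params(k_dge = 0.2, k_kill = 0)
  res <- run_simulation(dom, default_profile(), pr, n_cycles = 1, seed = 31)
  expect_true(all(diff(res$series$n_damaged) >= 0))
  expect_gt(tail(res$series$n_damaged, 1), 0)
})

test_that("an adjacent active effector with huge k_kill kills in one step", {
  sim <- mk_sim(seed = 12)
  sim$params$k_kill <- 1e6
  sim$params$c_act <- 0  # everything activates
  dmg <- sim$epi_ids[1]
  sim$state[dmg] <- EPI_STATES[["DAMAGED"]]
  nb <- node_neighbors(sim$domain, sim$node[dmg])
  nb <- nb[sim$occ[nb] == 0L &
             sim$domain$comp_v[nb] != COMPARTMENTS[["LUMEN"]]]
  spawn_immune(sim, nb[1], state = IMM_STATES[["ACTIVE"]])
  step_simulation(sim)
  expect_equal(sim$state[dmg], EPI_STATES[["DYING"]])
})
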