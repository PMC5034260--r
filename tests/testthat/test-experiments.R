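test_that("replicates are seed-reproducible with coherent pooling", {
  cfg <- sim_config(small_domain(), default_profile(), quick_params(),
                    master_seed = 99)
  a <- run_replicates(cfg, n_reps = 2, n_cycles = 1)
  b <- run_replicates(cfg, n_reps = 2, n_cycles = 1)
  expect_identical(a$series, b$series)
  expect_false(identical(a$series[[1]], a$series[[2]]))  # independent streams
  # pooled mean lies within the min/max envelopes
  expect_true(all(a$pooled$rel_eff_mean >= a$pooled$rel_eff_min - 1e-12))
  expect_true(all(a$pooled$rel_eff_mean <= a$pooled$rel_eff_max + 1e-12))
  # doubling the cycle count doubles the series length
  c2 <- run_replicates(cfg, n_reps = 1, n_cycles = 2)
  expect_equal(nrow(c2$series[[1]]), 2 * nrow(a$series[[1]]))
})

test_that("phase means use the calibration day windows", {
  t_h <- seq(1, 28 * 24 * 2)
  ts <- data.frame(t_h = t_h, rel_eff = 0.3, rel_reg = 0.5)
  pm <- phase_means(ts)
  expect_equal(unname(pm[c("follicular", "inbetween", "luteal")]),
               rep(0.3, 3))
  expect_equal(pm[["regulatory_all"]], 0.5)
  # a pulse confined to days 17-28 only moves the luteal mean
  day <- (t_h / 24) %% 28
  ts$rel_eff <- ifelse(day >= 17, 1, 0)
  pm <- phase_means(ts)
  expect_equal(pm[["luteal"]], 1)
  expect_equal(pm[["follicular"]], 0)
  expect_equal(pm[["inbetween"]], 0)
  expect_error(phase_means(ts[1:100, ]), "one cycle")
})

test_that("PI/AI samples match their analytic expectations", {
  dom <- test_domain()
  p <- default_profile()
  pr <- simulation_params()
  res <- run_simulation(dom, p, pr, n_cycles = 2, seed = 17)
  ro <- pi_ai_readout(res$series, p, pr)
  # total division commitments: Poisson-thinned sum, compare within 3 SE
  tot_exp <- sum(ro$pi_expected * res$series$n_epi / 1000)
  tot_obs <- sum(ro$pi_sample * res$series$n_epi / 1000)
  expect_lt(abs(tot_obs - tot_exp) / sqrt(tot_exp), 3.5)
  ai_exp <- sum(ro$ai_expected * res$series$n_epi / 1000)
  ai_obs <- sum(ro$ai_sample * res$series$n_epi / 1000)
  expect_lt(abs(ai_obs - ai_exp) / sqrt(ai_exp), 3.5)
  # zero-proliferation interval gives zero samples
  pz <- hormone_profile(p$t_grid, rep(0, length(p$t_grid)), p$f_ai)
  rz <- run_simulation(small_domain(), pz, quick_params(), n_cycles = 1,
                       seed = 18)
  expect_true(all(rz$series$pi_sample == 0))
})

test_that("the regime classifier separates the three inflammation regimes", {
  baseline <- fake_report(0, cyc_min = rep(0.08, 6))
  expect_equal(classify_regime(baseline, baseline), "PHYSIOLOGICAL")
  # never returns to baseline in any cycle -> chronic
  chronic <- fake_report(0.3, cyc_min = rep(0.4, 6), mean_dmg = 0.2)
  expect_equal(classify_regime(chronic, baseline, linear_resid = 2),
               "CHRONIC")
  # resolves each cycle but off the linear damage segment -> severe
  severe <- fake_report(0.15, cyc_min = rep(0.09, 6), mean_dmg = 0.08)
  expect_equal(classify_regime(severe, baseline, linear_resid = 0.5),
               "SEVERE")
  # on the linear segment and resolving -> physiological
  phys <- fake_report(0.05, cyc_min = rep(0.09, 6))
  expect_equal(classify_regime(phys, baseline, linear_resid = 0.02),
               "PHYSIOLOGICAL")
  expect_error(classify_regime(phys, NULL), "baseline")
})

test_that("classify_sweep fits the low-damage linear reference per group", {
  reports <- list(
    fake_report(0, cyc_min = rep(0.08, 6)),
    fake_report(0.05, cyc_min = rep(0.09, 6)),          # linear: 0.05 * 0.1
    fake_report(0.1, cyc_min = rep(0.09, 6)),           # linear
    fake_report(0.3, cyc_min = rep(0.09, 6), mean_dmg = 0.3)  # 10x off line
  )
  sw <- list(reports = reports,
             results = data.frame(k_dge = c(0, 0.05, 0.1, 0.3)))
  out <- classify_sweep(sw)
  expect_equal(out$results$regime,
               c("PHYSIOLOGICAL", "PHYSIOLOGICAL", "PHYSIOLOGICAL", "SEVERE"))
})
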