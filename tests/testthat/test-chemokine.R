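# independent reference stencil: naive double loop over nodes
naive_step <- function(C, dom, D, lambda, s, sources, dt) {
  out <- C
  comp <- dom$compartment
  for (x in 1:dom$width) {
    for (y in 1:dom$height) {
      if (comp[x, y] == COMPARTMENTS[["LUMEN"]]) { out[x, y] <- 0; next }
      lap <- 0
      for (k in 1:4) {
        nx <- x + c(0, 0, -1, 1)[k]
        ny <- y + c(-1, 1, 0, 0)[k]
        if (nx >= 1 && nx <= dom$width && ny >= 1 && ny <= dom$height &&
            comp[nx, ny] != COMPARTMENTS[["LUMEN"]]) {
          lap <- lap + C[nx, ny] - C[x, y]
        }
      }
      out[x, y] <- C[x, y] + dt * (D * lap - lambda * C[x, y])
    }
  }
  out[sources] <- out[sources] + s * dt
  out
}

test_that("pure decay and uniform fields follow the closed forms", {
  dom <- tiny_domain()
  f <- chemokine_fields(dom, D_dam = 0, D_dying = 0,
                        lambda_dam = 0.3, lambda_dying = 0.3)
  adm <- admissible_nodes(dom)
  f$c_dam[adm] <- runif(length(adm))
  before <- f$c_dam
  f2 <- step_field(f, dom, dt = 1)
  expect_equal(f2$c_dam[adm], before[adm] * (1 - 0.3), tolerance = 1e-14)
  # uniform field, lambda = 0: discrete Laplacian vanishes
  g <- chemokine_fields(dom, lambda_dam = 0, lambda_dying = 0)
  g$c_dam[adm] <- 2.5
  g2 <- step_field(g, dom, dt = 0.04)
  expect_equal(g2$c_dam[adm], rep(2.5, length(adm)), tolerance = 1e-14)
})

test_that("stability violations are rejected naming the field", {
  dom <- tiny_domain()
  f <- chemokine_fields(dom)  # D = 5, lambda = 0.5 -> dt_max ~ 0.0488
  expect_error(step_field(f, dom, dt = 1), "c_dam")
  f$D_dam <- 0
  f$lambda_dam <- 0
  expect_error(step_field(f, dom, dt = 1), "c_dying")
})

test_that("point source mass balance matches the naive stencil over 100 steps", {
  dom <- tiny_domain()
  f <- chemokine_fields(dom, lambda_dam = 0, lambda_dying = 0)
  src <- stromal_nodes(dom)[5]
  dt <- 0.04
  ref <- f$c_dam
  for (i in 1:100) {
    f <- step_field(f, dom, sources_dam = src, dt = dt)
    ref <- naive_step(ref, dom, 5, 0, 1, src, dt)
  }
  expect_equal(f$c_dam, ref, tolerance = 1e-9)
  # zero-flux, no decay: mass grows by exactly s*dt per step
  expect_equal(sum(f$c_dam), 100 * 1 * dt, tolerance = 1e-9)
})

test_that("compiled substepping agrees with the reference single step", {
  dom <- small_domain()
  f <- chemokine_fields(dom)
  src_dam <- stromal_nodes(dom)[c(3, 40)]
  src_dy <- which(as.integer(dom$compartment) ==
                    COMPARTMENTS[["LUMINAL_EPITHELIUM"]])[1:2]
  f1 <- tdlusim:::advance_fields(f, dom, src_dam, src_dy, dt = 1)
  nsub <- tdlusim:::stable_substeps(5, 0.5, 1)
  f2 <- f
  for (i in seq_len(nsub)) {
    f2 <- step_field(f2, dom, src_dam, src_dy, dt = 1 / nsub)
  }
  expect_equal(f1$c_dam, f2$c_dam, tolerance = 1e-12)
  expect_equal(f1$c_dying, f2$c_dying, tolerance = 1e-12)
  expect_true(all(f1$c_dam >= 0) && all(f1$c_dying >= 0))
  expect_true(all(f1$c_dam[dom$compartment == COMPARTMENTS[["LUMEN"]]] == 0))
})

test_that("mass is conserved without decay and vanishes exponentially with it", {
  dom <- tiny_domain()
  f <- chemokine_fields(dom, lambda_dam = 0, lambda_dying = 0)
  adm <- admissible_nodes(dom)
  set.seed(99)
  f$c_dam[adm] <- runif(length(adm))
  m0 <- sum(f$c_dam)
  for (i in 1:1000) f <- step_field(f, dom, dt = 0.04)
  expect_equal(sum(f$c_dam), m0, tolerance = 1e-9)
  # with decay and no sources the field drops below any epsilon
  g <- chemokine_fields(dom, lambda_dam = 2, lambda_dying = 2)
  g$c_dam[adm] <- 1
  for (i in 1:200) g <- tdlusim:::advance_fields(g, dom, integer(), integer(), 1)
  expect_lt(max(g$c_dam), 1e-12)
})

test_that("local gradients equal direct neighbor differences", {
  dom <- small_domain()
  f <- chemokine_fields(dom)
  # linear ramp in x
  for (x in 1:dom$width) f$c_dam[x, ] <- 0.1 * x
  f$c_dam[dom$compartment == COMPARTMENTS[["LUMEN"]]] <- 0
  node <- stromal_nodes(dom)[20]
  gr <- local_gradient(f, dom, node)
  xy <- tdlusim:::idx_to_xy(c(node, gr$neighbors), dom$width)
  dx <- xy[-1, 1] - xy[1, 1]
  lum_nb <- dom$comp_v[gr$neighbors] == COMPARTMENTS[["LUMEN"]]
  expect_equal(gr$d_dam[!lum_nb], 0.1 * dx[!lum_nb], tolerance = 1e-12)
  # uniform field: all differences zero
  f$c_dying[] <- 1
  f$c_dying[dom$compartment == COMPARTMENTS[["LUMEN"]]] <- 0
  nb_ok <- gr$neighbors[dom$comp_v[gr$neighbors] != COMPARTMENTS[["LUMEN"]]]
  gr2 <- local_gradient(f, dom, node)
  expect_true(all(abs(gr2$d_dying[match(nb_ok, gr2$neighbors)]) < 1e-14))
  # random patch against brute-force recomputation
  set.seed(4)
  f$c_dam[] <- runif(length(f$c_dam))
  gr3 <- local_gradient(f, dom, node)
  expect_equal(gr3$d_dam, f$c_dam[gr3$neighbors] - f$c_dam[node])
  expect_error(local_gradient(f, dom,
                              which(dom$compartment == COMPARTMENTS[["LUMEN"]])[1]),
               "LUMEN")
})
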