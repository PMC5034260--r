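test_that("g(r) matches the brute-force pair census oracle", {
  dom <- tiny_domain()
  set.seed(41)
  idx <- sample(admissible_nodes(dom), 20)
  rdf <- radial_distribution(idx, dom, r_max = 8)
  expect_equal(rdf$g, naive_g(idx, dom, 8), tolerance = 1e-12)
  # two points at a known distance: g nonzero only in that bin
  adm <- admissible_nodes(dom)
  xy <- tdlusim:::idx_to_xy(adm, dom$width)
  i <- 1
  j <- which(xy[, 1] == xy[i, 1] + 3 & xy[, 2] == xy[i, 2])[1]
  rdf2 <- radial_distribution(adm[c(i, j)], dom, r_max = 8)
  expect_equal(which(rdf2$g > 0), 4L)  # bin [3, 4)
  expect_equal(rdf2$g, naive_g(adm[c(i, j)], dom, 8), tolerance = 1e-12)
  expect_error(radial_distribution(adm[1], dom), "2 points")
})

test_that("CSR patterns give g ~ 1 and a tight cluster gives small-r excess", {
  dom <- test_domain()
  gs <- replicate(20, {
    pts <- make_synthetic_pattern("csr", 500, dom,
                                  seed = sample.int(1e6, 1))
    mean(radial_distribution(pts, dom, r_max = 20)$g, na.rm = TRUE)
  })
  expect_lt(abs(mean(gs) - 1), 0.05)
  # one tight block of cells: g >> 1 at small r, < 1 at large r
  st <- stromal_nodes(dom)
  xy <- tdlusim:::idx_to_xy(st, dom$width)
  ctr <- st[order((xy[, 1] - 10)^2 + (xy[, 2] - 10)^2)][1:12]
  rdf <- radial_distribution(ctr, dom, r_max = 20)
  expect_gt(rdf$g[2], 5)  # first bin with pair distances (r in [1, 2))
  expect_lt(mean(rdf$g[15:20], na.rm = TRUE), 1)
})

test_that("power-law fits recover exact and noisy parameters", {
  r <- 1:50
  fit <- fit_power_law(r, 2 * r^-1.5)
  expect_equal(fit$b, 2, tolerance = 1e-12)
  expect_equal(fit$m, 1.5, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  flat <- fit_power_law(r, rep(1, 50))
  expect_equal(flat$m, 0, tolerance = 1e-12)
  expect_equal(flat$b, 1, tolerance = 1e-12)
  # scale covariance: g -> c * g multiplies b by c, leaves m unchanged
  f2 <- fit_power_law(r, 3 * (2 * r^-1.5))
  expect_equal(f2$b, 6, tolerance = 1e-10)
  expect_equal(f2$m, 1.5, tolerance = 1e-10)
  # multiplicative lognormal noise: m recovered within +/- 0.1
  set.seed(77)
  for (k in 1:100) {
    g <- 2 * r^-1.2 * exp(rnorm(50, 0, 0.1))
    expect_lt(abs(fit_power_law(r, g)$m - 1.2), 0.1)
  }
  expect_error(fit_power_law(r, rep(0, 50)), "zero")
  expect_error(fit_power_law(1:2, c(1, 2)), "3 positive bins")
})

test_that("contact profiles tally cells by epithelium distance bands", {
  dom <- small_domain()
  d <- as.integer(dom$dist_epi)
  band1 <- which(d == 1L)
  cp <- contact_profile(band1, dom, n_epithelial = 50)
  expect_equal(cp$count, c(0L, length(band1), 0L, 0L))
  expect_equal(cp$relative[2], length(band1) / 50)
  empty <- contact_profile(matrix(numeric(0), ncol = 2), dom)
  expect_equal(empty$count, rep(0L, 4))
  # random placement matches a direct tally
  set.seed(9)
  pts <- sample(admissible_nodes(dom), 40)
  cp2 <- contact_profile(pts, dom)
  tal <- table(factor(pmin(d[pts], 3L), levels = 0:3))
  expect_equal(cp2$count, as.integer(tal))
})

test_that("cluster detection agrees with a union-find oracle", {
  dom <- small_domain()
  # pairwise non-adjacent points: no cluster at the default threshold
  st <- stromal_nodes(dom)
  xy <- tdlusim:::idx_to_xy(st, dom$width)
  sparse <- st[!duplicated(paste(xy[, 1] %/% 3, xy[, 2] %/% 3))][1:8]
  expect_equal(cluster_stats(sparse, dom)$n_clusters, 0L)
  # a 3x3 block is one cluster of size 9
  block <- as.matrix(expand.grid(x = 2:4, y = 2:4))
  cs <- cluster_stats(block, dom)
  expect_equal(cs$n_clusters, 1L)
  expect_equal(cs$sizes, 9L)
  # random patterns: component structure equals union-find on 100 draws
  set.seed(55)
  for (k in 1:100) {
    pts <- sample(admissible_nodes(dom), 25)
    pxy <- tdlusim:::idx_to_xy(pts, dom$width)
    cs <- cluster_stats(pts, dom, cluster_min = 1)
    oracle <- uf_components(pxy)
    expect_equal(cs$n_clusters, length(unique(oracle)))
    expect_equal(sort(cs$sizes), sort(as.integer(table(oracle))))
    # same partition up to labelling
    expect_equal(length(unique(paste(cs$membership, oracle))),
                 length(unique(oracle)))
  }
})
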