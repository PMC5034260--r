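test_that("single-acinus rings match brute-force enumeration", {
  dom <- tiny_domain()
  cx <- dom$acini$x[1]
  cy <- dom$acini$y[1]
  grid <- expand.grid(x = 1:dom$width, y = 1:dom$height)
  d2 <- (grid$x - cx)^2 + (grid$y - cy)^2
  lumen <- which(d2 <= 4)
  # brute-force 4-neighborhood dilation of the lumen disc
  adj4 <- function(set) {
    out <- integer()
    for (i in set) {
      x <- grid$x[i]; y <- grid$y[i]
      for (k in 1:4) {
        nx <- x + c(0, 0, -1, 1)[k]
        ny <- y + c(-1, 1, 0, 0)[k]
        if (nx >= 1 && nx <= dom$width && ny >= 1 && ny <= dom$height) {
          out <- c(out, nx + (ny - 1) * dom$width)
        }
      }
    }
    unique(out)
  }
  luminal_expect <- setdiff(adj4(lumen), lumen)
  comp <- as.integer(dom$compartment)
  expect_setequal(which(comp == COMPARTMENTS[["LUMEN"]]), lumen)
  expect_setequal(which(comp == COMPARTMENTS[["LUMINAL_EPITHELIUM"]]),
                  luminal_expect)
  myo_expect <- setdiff(adj4(c(lumen, luminal_expect)), c(lumen, luminal_expect))
  expect_setequal(which(comp == COMPARTMENTS[["MYOEPITHELIUM"]]), myo_expect)
})

test_that("infeasible geometries raise explicit errors", {
  expect_error(build_tdlu(n_acini = 0), "n_acini")
  expect_error(build_tdlu(n_acini = 4, acinus_spacing = 3, grid_size = 30,
                          epi_band = NULL),
               "geometry-infeasible")
  expect_error(build_tdlu(n_acini = 1, lumen_radius = 6, grid_size = 10,
                          epi_band = NULL),
               "geometry-infeasible")
  expect_error(build_tdlu(n_acini = 1, grid_size = 20, epi_band = c(250, 2500)),
               "band")
})

test_that("structural invariants hold across seeds and rebuilds are identical", {
  for (s in 1:4) {
    dom <- build_tdlu(n_acini = 5, acinus_spacing = 10, grid_size = 42,
                      seed = s, epi_band = NULL)
    expect_true(validate_domain(dom))
    # no lumen node has a stromal Moore neighbor
    comp <- c(as.integer(dom$compartment), COMPARTMENTS[["LUMEN"]])
    lum <- which(comp[seq_len(dom$width * dom$height)] == COMPARTMENTS[["LUMEN"]])
    nb_comp <- matrix(comp[dom$nb_moore[lum, ]], nrow = length(lum))
    expect_false(any(nb_comp >= COMPARTMENTS[["INTRALOBULAR_STROMA"]]))
  }
  a <- build_tdlu(n_acini = 5, acinus_spacing = 10, grid_size = 42, seed = 7,
                  epi_band = NULL)
  b <- build_tdlu(n_acini = 5, acinus_spacing = 10, grid_size = 42, seed = 7,
                  epi_band = NULL)
  expect_identical(a$compartment, b$compartment)
  expect_identical(a$tdlu_polygon, b$tdlu_polygon)
})

test_that("distance map equals a brute-force BFS oracle", {
  dom <- small_domain()
  comp <- as.integer(dom$compartment)
  n <- dom$width * dom$height
  blocked <- comp == COMPARTMENTS[["LUMEN"]]
  seedset <- which(comp %in% COMPARTMENTS[c("LUMINAL_EPITHELIUM", "MYOEPITHELIUM")])
  # plain queue BFS over Moore neighbors
  d <- rep(NA_integer_, n)
  d[seedset] <- 0L
  queue <- seedset
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    for (nb in node_neighbors(dom, cur, "moore")) {
      if (!blocked[nb] && is.na(d[nb])) {
        d[nb] <- d[cur] + 1L
        queue <- c(queue, nb)
      }
    }
  }
  expect_identical(as.integer(dom$dist_epi), d)
  expect_true(all(dom$dist_epi[seedset] == 0L))
  stroma_adj <- setdiff(
    unique(as.vector(dom$nb_moore[seedset, ])[as.vector(dom$nb_moore[seedset, ]) <= n]),
    c(seedset, which(blocked))
  )
  expect_true(all(dom$dist_epi[stroma_adj] == 1L))
})

test_that("domain TSV round-trips exactly", {
  dom <- tiny_domain()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_domain_tsv(dom, path)
  m <- read_domain_tsv(path)
  expect_identical(m, dom$compartment)
})
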