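# Shared fixtures: domains are deterministic in their seed, so build each
# once per test run and reuse.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# one acinus, 16x16: small enough for brute-force oracles
tiny_domain <- function() {
  cached("tiny", build_tdlu(n_acini = 1, lumen_radius = 2, acinus_spacing = 8,
                            grid_size = 16, seed = 1, epi_band = NULL))
}

# two acini, 26x26: room for stroma and immune movement
small_domain <- function() {
  cached("small", build_tdlu(n_acini = 2, lumen_radius = 2, acinus_spacing = 9,
                             grid_size = 26, seed = 3, epi_band = NULL))
}

# 9 acini, 252 epithelial nodes: inside the quantification band, used for
# simulation-level tests
test_domain <- function() {
  cached("test", build_tdlu(n_acini = 9, lumen_radius = 2, acinus_spacing = 9,
                            grid_size = 48, seed = 1))
}

# quick engine parameters for short runs
quick_params <- function(...) {
  simulation_params(..., debug = TRUE)
}

# independent union-find (disjoint-set) oracle for cluster detection
uf_components <- function(xy) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && max(abs(xy[i, ] - xy[j, ])) <= 1) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}
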