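# Independent oracles shared across test files.

# brute-force pair-correlation estimate: direct census of admissible node
# pairs and observed pairs, no chunking or caching
naive_g <- function(idx, dom, r_max, bw = 1) {
  adm <- admissible_nodes(dom)
  axy <- tdlusim:::idx_to_xy(adm, dom$width)
  n_bins <- ceiling(r_max / bw)
  census <- numeric(n_bins)
  for (i in seq_along(adm)) {
    for (j in seq_along(adm)) {
      if (i < j) {
        d <- sqrt(sum((axy[i, ] - axy[j, ])^2))
        if (d < r_max) {
          b <- min(floor(d / bw) + 1, n_bins)
          census[b] <- census[b] + 1
        }
      }
    }
  }
  xy <- tdlusim:::idx_to_xy(idx, dom$width)
  obs <- numeric(n_bins)
  n <- length(idx)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
        if (d < r_max) {
          b <- min(floor(d / bw) + 1, n_bins)
          obs[b] <- obs[b] + 1
        }
      }
    }
  }
  N <- length(adm)
  expected <- census * n * (n - 1) / (N * (N - 1))
  ifelse(expected > 0, obs / expected, NA_real_)
}

# a synthetic one-point regime report for classifier tests
fake_report <- function(k_dge, cyc_min, mean_dmg = k_dge * 0.1,
                        mean_imm = 0.1, sd_imm = 0.01, max_imm = 0.13) {
  list(k_dge = k_dge, k_kill = 0.1, theta = 1, follicular_len = 14,
       mean_rel_damaged = mean_dmg, mean_rel_eff = mean_imm / 2,
       mean_rel_reg = mean_imm / 2, mean_rel_immune = mean_imm,
       amplitude_immune = 0.05, reg_minus_eff = 0,
       cycle_min_rel_imm = cyc_min, cycle_max_rel_imm = cyc_min + 0.1,
       sd_rel_imm = sd_imm, max_rel_imm = max_imm,
       mean_n_clusters = 0, n_excluded = 0, snapshots = list(),
       regime = NA_character_)
}
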