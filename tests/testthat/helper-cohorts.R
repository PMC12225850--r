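# Fixture builders shared across tests. All cohorts are generated in code;
# seeds are fixed by the caller.

# random valid lipid panels with measured LDL-C; vldl_c > 0 by construction
random_panels <- function(n, seed) {
  set.seed(seed)
  nonhdl <- runif(n, 80, 250)
  hdl <- runif(n, 30, 80)
  tg <- runif(n, 5, 399)
  ratio <- runif(n, 2, 9)
  vldl <- tg / ratio
  keep <- vldl < nonhdl
  data.frame(id = seq_len(n), tc = nonhdl + hdl, hdl_c = hdl, tg = tg,
             ldl_d = nonhdl - vldl)[keep, , drop = FALSE]
}

# one six_tg cell's worth of rows with a constant true ratio times noise
cell_cohort <- function(n, tg_lo, tg_hi, true_ratio, noise_sd, seed,
                        nonhdl_lo = 150, nonhdl_hi = 250) {
  set.seed(seed)
  tg <- runif(n, tg_lo, tg_hi)
  nonhdl <- runif(n, nonhdl_lo, nonhdl_hi)
  hdl <- runif(n, 35, 70)
  r <- true_ratio * exp(rnorm(n, 0, noise_sd))
  data.frame(id = seq_len(n), tc = nonhdl + hdl, hdl_c = hdl, tg = tg,
             ldl_d = nonhdl - tg / r)
}

# independent exhaustive grid-scan oracle for the optimal AF of one cell
oracle_optimal_af <- function(nonhdl, tg, ldl_d, grid) {
  meas <- ncep_index(ldl_d)
  conc <- vapply(grid, function(v) sum(ncep_index(nonhdl - tg / v) == meas), 1L)
  list(af = grid[which.max(conc)], conc = conc)
}

# independent exhaustive order-statistic scan for the median CI ranks:
# among all symmetric rank pairs, the narrowest with exact binomial
# coverage >= conf, falling back to the sample extremes
oracle_median_ci_ranks <- function(n, conf = 0.95) {
  ls <- seq_len(floor((n + 1) / 2))
  cov <- vapply(ls, function(l) pbinom(n - l, n, 0.5) - pbinom(l - 1, n, 0.5), 1.0)
  ok <- which(cov >= conf)
  l <- if (length(ok)) max(ok) else 1L
  list(l = l, u = n + 1L - l, acl = cov[l])
}
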