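# Synthetic lipid cohorts with the joint structure the analysis assumes:
# right-skewed TG and non-HDL-C marginals (lognormal, parameterized by
# median and IQR), coupled by a Gaussian copula; a TG/VLDL-C ratio surface
# that rises with TG and falls with non-HDL-C (log-linear, or a cell-wise
# constant truth table); multiplicative lognormal ratio noise; HDL-C from
# its own marginal. Directly measured LDL-C is then consistent by
# construction: vldl = tg / ratio, ldl_d = non_hdl - vldl, tc = non_hdl +
# hdl.

#' Synthetic cohort configuration
#'
#' @param n Number of individuals.
#' @param seed RNG seed (integer); cohorts are bit-identical for a fixed
#'   seed.
#' @param tg_median,tg_iqr TG marginal target: median and `c(q1, q3)`,
#'   mg/dL.
#' @param tg_range Truncation range for TG, mg/dL (half-open).
#' @param nonhdl_median,nonhdl_iqr Non-HDL-C marginal target, mg/dL.
#' @param hdl_median,hdl_iqr HDL-C marginal target, mg/dL.
#' @param tg_nonhdl_dependence Spearman rank correlation between TG and
#'   non-HDL-C, in `[-1, 1]`.
#' @param ratio_base,ratio_tg_slope,ratio_nonhdl_slope Log-linear true
#'   ratio surface `r = base + tg_slope * log(tg) - nonhdl_slope *
#'   log(nonhdl)`.
#' @param ratio_noise_sd Lognormal sigma of multiplicative ratio noise.
#' @param ratio_table Optional `ratio_table` supplying a cell-wise
#'   constant true ratio surface instead of the log-linear one (the AF of
#'   the individual's cell, times noise).
#' @param ratio_clamp True ratios are clamped to this open interval
#'   (default `c(1, 12)`).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n, seed,
                         tg_median = 156, tg_iqr = c(86, 237),
                         tg_range = c(0, 400),
                         nonhdl_median = 142, nonhdl_iqr = c(116, 169),
                         hdl_median = 46, hdl_iqr = c(39, 54),
                         tg_nonhdl_dependence = 0.35,
                         ratio_base = 4.0, ratio_tg_slope = 1.5,
                         ratio_nonhdl_slope = 1.2,
                         ratio_noise_sd = 0.25,
                         ratio_table = NULL,
                         ratio_clamp = c(1, 12)) {
  if (n < 1) stop_config("n must be at least 1")
  if (abs(tg_nonhdl_dependence) > 1) {
    stop_config("tg_nonhdl_dependence must lie in [-1, 1]")
  }
  if (!is.null(ratio_table)) stopifnot(inherits(ratio_table, "ratio_table"))
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         tg_median = tg_median, tg_iqr = tg_iqr, tg_range = tg_range,
         nonhdl_median = nonhdl_median, nonhdl_iqr = nonhdl_iqr,
         hdl_median = hdl_median, hdl_iqr = hdl_iqr,
         tg_nonhdl_dependence = tg_nonhdl_dependence,
         ratio_base = ratio_base, ratio_tg_slope = ratio_tg_slope,
         ratio_nonhdl_slope = ratio_nonhdl_slope,
         ratio_noise_sd = ratio_noise_sd,
         ratio_table = ratio_table, ratio_clamp = ratio_clamp),
    class = "synth_config"
  )
}

#' Preset cohort configurations
#'
#' `population1` emulates a general-screening TG distribution (median 102,
#' IQR 69-150 mg/dL); `population2` a moderate-hypertriglyceridemia sample
#' restricted to TG 200-399 mg/dL (median 247, IQR 219-291); `combined`
#' mixes the two at their study sample sizes (11,930 : 6,392 by default).
#' Non-HDL-C and HDL-C marginals follow the corresponding published
#' medians/IQRs.
#'
#' @param name `"population1"`, `"population2"` or `"combined"`.
#' @param n Cohort size (defaults: 11930, 6392, 18322).
#' @param seed RNG seed.
#' @param weights For `combined`, the two mixture weights.
#' @param ... Overrides passed to [synth_config()] (e.g. `ratio_table`).
#' @return A `synth_config`, or for `combined` a `synth_config_mix`.
#' @export
synth_preset <- function(name, n = NULL, seed = 1,
                         weights = c(11930, 6392), ...) {
  p1 <- function(n) synth_config(
    n = n, seed = seed,
    tg_median = 102, tg_iqr = c(69, 150), tg_range = c(0, 400),
    nonhdl_median = 132, nonhdl_iqr = c(109, 158),
    hdl_median = 49, hdl_iqr = c(42, 57), ...)
  p2 <- function(n) synth_config(
    n = n, seed = seed,
    tg_median = 247, tg_iqr = c(219, 291), tg_range = c(200, 399),
    nonhdl_median = 161, nonhdl_iqr = c(138, 187),
    hdl_median = 42, hdl_iqr = c(37, 48), ...)
  switch(name,
    population1 = p1(if (is.null(n)) 11930 else n),
    population2 = p2(if (is.null(n)) 6392 else n),
    combined = {
      n_tot <- if (is.null(n)) sum(round(weights)) else n
      n1 <- round(n_tot * weights[1] / sum(weights))
      structure(list(components = list(p1(n1), p2(n_tot - n1)),
                     seed = as.integer(seed), n = as.integer(n_tot)),
                class = c("synth_config_mix", "synth_config"))
    },
    stop_config(paste0("unknown preset '", name,
                       "'; valid names: population1, population2, combined"))
  )
}

# lognormal sdlog implied by a median/IQR target
sdlog_from_iqr <- function(iqr) log(iqr[2] / iqr[1]) / (2 * qnorm(0.75))

# (meanlog, sdlog) such that the range-truncated lognormal hits the target
# median and IQR; deterministic Nelder-Mead from the untruncated solution
calibrate_trunc_lnorm <- function(med, iqr, range) {
  start <- c(log(med), sdlog_from_iqr(iqr))
  f_rng <- function(par) plnorm(pmax(range, 0), par[1], par[2])
  loss <- function(par) {
    if (par[2] <= 0) return(Inf)
    fr <- f_rng(par)
    q <- qlnorm(fr[1] + c(0.25, 0.5, 0.75) * (fr[2] - fr[1]), par[1], par[2])
    sum((q - c(iqr[1], med, iqr[2]))^2)
  }
  if (loss(start) < 1e-6) return(start)  # no effective truncation
  stats::optim(start, loss, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))$par
}

# one batch of candidate rows (before positivity filtering)
draw_batch <- function(config, m) {
  tg_par <- calibrate_trunc_lnorm(config$tg_median, config$tg_iqr,
                                  config$tg_range)
  mlog_tg <- tg_par[1]
  slog_tg <- tg_par[2]
  mlog_nh <- log(config$nonhdl_median)
  slog_nh <- sdlog_from_iqr(config$nonhdl_iqr)
  mlog_hd <- log(config$hdl_median)
  slog_hd <- sdlog_from_iqr(config$hdl_iqr)
  rho <- 2 * sin(pi * config$tg_nonhdl_dependence / 6)  # Spearman -> Gaussian
  z1 <- rnorm(m)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
  # TG: inverse-CDF sampling restricted to the truncation range
  f_lo <- plnorm(max(config$tg_range[1], 0), mlog_tg, slog_tg)
  f_hi <- plnorm(config$tg_range[2], mlog_tg, slog_tg)
  tg <- qlnorm(f_lo + pnorm(z1) * (f_hi - f_lo), mlog_tg, slog_tg)
  tg <- pmin(tg, config$tg_range[2] * (1 - 1e-12))     # guard the open bound
  nonhdl <- qlnorm(pnorm(z2), mlog_nh, slog_nh)
  hdl <- qlnorm(runif(m), mlog_hd, slog_hd)
  if (is.null(config$ratio_table)) {
    r <- config$ratio_base +
      config$ratio_tg_slope * log(tg) -
      config$ratio_nonhdl_slope * log(nonhdl)
  } else {
    r <- lookup_af(config$ratio_table, tg, nonhdl)
  }
  if (config$ratio_noise_sd > 0) r <- r * exp(rnorm(m, 0, config$ratio_noise_sd))
  r <- pmin(pmax(r, config$ratio_clamp[1]), config$ratio_clamp[2])
  vldl <- tg / r
  data.frame(tc = nonhdl + hdl, hdl_c = hdl, tg = tg,
             ldl_d = nonhdl - vldl)
}

#' Generate a synthetic lipid cohort
#'
#' Deterministic for a fixed seed. Rows violating positivity
#' (`ldl_d <= 0`) are rejection-resampled; generation aborts if the total
#' number of draws exceeds 100 times the requested size.
#'
#' @param config A `synth_config` or `synth_config_mix` (see
#'   [synth_preset()]).
#' @return A lipid cohort data.frame with columns
#'   `id, tc, hdl_c, tg, ldl_d`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  parts <- if (inherits(config, "synth_config_mix")) config$components
           else list(config)
  rows <- lapply(parts, generate_component)
  out <- do.call(rbind, rows)
  out <- cbind(id = sprintf("S%06d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

# draws for one (non-mixture) component; assumes the RNG is already seeded
generate_component <- function(config) {
  kept <- NULL
  drawn <- 0L
  need <- config$n
  while (need > 0) {
    m <- max(need * 2L, 100L)
    if (drawn + m > 100L * config$n) {
      stop_derivation(paste0(
        "cohort generation exceeded the retry budget; the configuration ",
        "forces vldl_c >= non_hdl for most draws (infeasible ratio surface)"))
    }
    batch <- draw_batch(config, m)
    drawn <- drawn + m
    ok <- batch$ldl_d > 0
    kept <- rbind(kept, batch[ok, , drop = FALSE])
    need <- config$n - nrow(kept)
  }
  kept[seq_len(config$n), , drop = FALSE]
}
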