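# Derivation of strata-specific TG/VLDL-C ratio tables from a cohort with
# directly measured LDL-C: sample medians with distribution-free CIs, and
# concordance-optimal values found by exhaustive grid search.

#' The AF search grid
#'
#' Candidate adjustable factors from `lo` to `hi` in steps of `step`
#' (default 1.0 to 10.0 by 0.1, i.e. 91 values). Values are generated as
#' scaled integers so each grid point is exactly the number it prints as.
#'
#' @param lo,hi,step Grid bounds and resolution.
#' @return Numeric vector of grid values.
#' @export
ratio_grid <- function(lo = 1, hi = 10, step = 0.1) {
  scale <- round(1 / step)
  k_lo <- round(lo * scale); k_hi <- round(hi * scale)
  if (k_hi <= k_lo) stop_config("ratio grid must have hi > lo")
  (k_lo:k_hi) / scale
}

#' Distribution-free confidence interval for a median
#'
#' Order-statistic interval `(x[(l)], x[(u)])` with symmetric ranks
#' `u = n + 1 - l`, choosing the narrowest symmetric pair whose exact
#' binomial coverage `P(l <= B <= u - 1)`, `B ~ Binomial(n, 1/2)`, is at
#' least `conf`. When no symmetric pair attains `conf` (small `n`) the
#' interval widens to the sample extremes and the achieved coverage is
#' reported as-is. The achieved confidence level (ACL) generally exceeds
#' the nominal level.
#'
#' @param x Numeric sample.
#' @param conf Nominal confidence level (default 0.95).
#' @return List with `median`, `lo`, `hi`, `acl` (achieved coverage), and
#'   the ranks `l`, `u`.
#' @export
median_ci <- function(x, conf = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1) stop_derivation("median_ci needs at least one observation")
  s <- sort(x)
  coverage <- function(l) {
    u <- n + 1L - l
    if (u <= l - 1L) return(0)
    pbinom(u - 1L, n, 0.5) - pbinom(l - 1L, n, 0.5)
  }
  l_max <- floor((n + 1) / 2)
  l <- 1L
  for (cand in rev(seq_len(l_max))) {   # narrowest symmetric pair first
    if (coverage(cand) >= conf) { l <- cand; break }
  }
  u <- n + 1L - l
  list(median = median(s), lo = s[l], hi = s[u],
       acl = coverage(l), l = l, u = u)
}

# Per-cell concordant / under / over counts across the whole grid.
# Returns list of three (n_cells x n_grid) matrices. The estimator is
# strictly increasing in af (tg > 0), so along the grid under-counts are
# non-increasing and over-counts non-decreasing.
grid_counts <- function(non_hdl, tg, meas_idx, cell, k_cells, grid) {
  n_g <- length(grid)
  conc <- under <- over <- matrix(0L, nrow = k_cells, ncol = n_g)
  f <- factor(cell, levels = seq_len(k_cells))
  for (j in seq_len(n_g)) {
    est_idx <- findInterval(non_hdl - tg / grid[j], NCEP_BREAKS)
    d <- est_idx - meas_idx
    conc[, j] <- tabulate(as.integer(f)[d == 0], nbins = k_cells)
    under[, j] <- tabulate(as.integer(f)[d < 0], nbins = k_cells)
    over[, j] <- tabulate(as.integer(f)[d > 0], nbins = k_cells)
  }
  list(conc = conc, under = under, over = over)
}

#' Derive a median ratio table
#'
#' Per-cell sample median of the TG/VLDL-C ratio (rounded to the 0.1 grid
#' resolution for storage) with a distribution-free 95% CI from order
#' statistics and its achieved confidence level. Individuals whose ratio
#' is undefined (`vldl_c <= 0`) are excluded from derivation; their count
#' is messaged.
#'
#' @param cohort A lipid cohort with directly measured LDL-C.
#' @param scheme A `strat_scheme`.
#' @param conf Nominal confidence level for the median CIs.
#' @param min_n Per-cell sample-size floor below which a warning is issued.
#' @return A `ratio_table` with `statistic = "median"`.
#' @export
median_ratio_table <- function(cohort, scheme, conf = 0.95, min_n = 100) {
  validate_cohort(cohort, require_ldl_d = TRUE)
  cohort <- derive_panel(cohort)
  n_undef <- attr(cohort, "n_undefined_ratio")
  if (n_undef > 0) {
    message(sprintf("excluding %d individuals with undefined TG/VLDL-C ratio (vldl_c <= 0)",
                    n_undef))
  }
  usable <- !is.na(cohort$tg_vldl_ratio)
  cell <- assign_cell(scheme, cohort$tg[usable], cohort$non_hdl[usable])
  ratio <- cohort$tg_vldl_ratio[usable]
  cells <- scheme_cells(scheme)
  k <- nrow(cells)
  af <- ci_lo <- ci_hi <- acl <- numeric(k)
  n_cell <- tabulate(cell, nbins = k)
  for (i in seq_len(k)) {
    if (n_cell[i] == 0) {
      stop_derivation(sprintf(
        "cell %d (TG [%g, %g), non-HDL-C [%g, %g)) is empty; cannot derive a median ratio",
        i, cells$tg_lo[i], cells$tg_hi[i], cells$nonhdl_lo[i], cells$nonhdl_hi[i]))
    }
    ci <- median_ci(ratio[cell == i], conf = conf)
    af[i] <- round(ci$median, 1)
    ci_lo[i] <- ci$lo; ci_hi[i] <- ci$hi; acl[i] <- ci$acl
  }
  if (any(n_cell < min_n)) {
    warning(sprintf("%d cells have fewer than %d usable samples",
                    sum(n_cell < min_n), min_n), call. = FALSE)
  }
  ratio_table(scheme, "median", pmin(pmax(af, 1), 10),
              n = n_cell, ci_lo = ci_lo, ci_hi = ci_hi, acl = acl)
}

#' Derive a concordance-optimal ratio table
#'
#' For each cell, scans the grid and keeps the AF that maximizes the count
#' of cell members whose estimated category (`non_hdl - tg / af`) equals
#' their directly measured category; ties break to the lowest grid value
#' and are recorded in the `tie` column. The objective needs only
#' non-HDL-C, TG and the measured category, so individuals with an
#' undefined TG/VLDL-C ratio are included (and their count messaged).
#'
#' @param cohort A lipid cohort with directly measured LDL-C.
#' @param scheme A `strat_scheme`.
#' @param grid Candidate AF values, see [ratio_grid()].
#' @param min_n Per-cell sample-size floor below which a warning is issued.
#' @return A `ratio_table` with `statistic = "optimal"`; per-cell in-sample
#'   concordance proportions in attribute `concordance`.
#' @export
optimal_ratio_table <- function(cohort, scheme, grid = ratio_grid(),
                                min_n = 100) {
  validate_cohort(cohort, require_ldl_d = TRUE)
  cohort <- derive_panel(cohort)
  n_undef <- attr(cohort, "n_undefined_ratio")
  if (n_undef > 0) {
    message(sprintf("including %d individuals with undefined TG/VLDL-C ratio in the grid objective",
                    n_undef))
  }
  cells <- scheme_cells(scheme)
  k <- nrow(cells)
  cell <- assign_cell(scheme, cohort$tg, cohort$non_hdl)
  n_cell <- tabulate(cell, nbins = k)
  if (any(n_cell == 0)) {
    i <- which(n_cell == 0)[1]
    stop_derivation(sprintf(
      "cell %d (TG [%g, %g), non-HDL-C [%g, %g)) is empty; cannot derive an optimal ratio",
      i, cells$tg_lo[i], cells$tg_hi[i], cells$nonhdl_lo[i], cells$nonhdl_hi[i]))
  }
  meas_idx <- findInterval(cohort$ldl_d, NCEP_BREAKS)
  gc <- grid_counts(cohort$non_hdl, cohort$tg, meas_idx, cell, k, grid)
  best_j <- apply(gc$conc, 1, which.max)       # first maximum = lowest af
  best_n <- gc$conc[cbind(seq_len(k), best_j)]
  tie <- vapply(seq_len(k),
                function(i) sum(gc$conc[i, ] == best_n[i]) > 1, TRUE)
  if (any(n_cell < min_n)) {
    warning(sprintf("%d cells have fewer than %d samples",
                    sum(n_cell < min_n), min_n), call. = FALSE)
  }
  out <- ratio_table(scheme, "optimal", grid[best_j], n = n_cell, tie = tie)
  attr(out, "concordance") <- best_n / n_cell
  out
}

#' Concordance / discordance rates across the AF grid
#'
#' For one cell's cohort (or any cohort treated as a single cell), the
#' proportion of concordant, under-classified and over-classified
#' individuals at each grid value. The three rates sum to one everywhere;
#' under-classification is non-increasing and over-classification
#' non-decreasing in AF.
#'
#' @param cohort A lipid cohort with directly measured LDL-C.
#' @param grid Candidate AF values.
#' @return A data.frame: `af`, `concordance`, `under`, `over`.
#' @export
discordance_curve <- function(cohort, grid = ratio_grid()) {
  validate_cohort(cohort, require_ldl_d = TRUE)
  if (nrow(cohort) == 0) stop_input("cohort is empty")
  cohort <- derive_panel(cohort)
  meas_idx <- findInterval(cohort$ldl_d, NCEP_BREAKS)
  gc <- grid_counts(cohort$non_hdl, cohort$tg, meas_idx,
                    rep(1L, nrow(cohort)), 1L, grid)
  n <- nrow(cohort)
  data.frame(af = grid,
             concordance = gc$conc[1, ] / n,
             under = gc$under[1, ] / n,
             over = gc$over[1, ] / n)
}
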