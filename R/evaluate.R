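# Evaluation of estimated against directly measured LDL-C: guideline
# category concordance with exact inference, treatment-category
# reclassification, Bland-Altman agreement, and fit metrics.

#' Pair and classify estimated vs measured LDL-C
#'
#' Labels each individual `concordant` (same NCEP-ATP III category),
#' `under` (estimated category below the measured one) or `over`
#' (estimated above measured).
#'
#' @param estimates Either a numeric vector of estimates (aligned with
#'   `measured`) or an estimate-record data.frame with `id` and `estimate`
#'   columns (see [estimate_friedewald()]).
#' @param measured Either a numeric vector of directly measured LDL-C or a
#'   data.frame with `id` and `ldl_d` columns. When both arguments carry
#'   ids, rows are paired by id and unpaired ids are an error.
#' @return A data.frame: `id` (when available), `estimate`, `measured`,
#'   `est_cat`, `meas_cat` (ordered factors), `status`.
#' @export
classify <- function(estimates, measured) {
  id <- NULL
  if (is.data.frame(estimates)) {
    if (is.data.frame(measured)) {
      if (!all(c("id", "ldl_d") %in% names(measured))) {
        stop_input("measured data.frame needs 'id' and 'ldl_d' columns")
      }
      m <- match(estimates$id, measured$id)
      if (anyNA(m) || nrow(estimates) != nrow(measured)) {
        stop_input("estimates and measured do not pair one-to-one by id")
      }
      measured <- measured$ldl_d[m]
    }
    id <- estimates$id
    estimates <- estimates$estimate
  }
  if (length(estimates) != length(measured)) {
    stop_input("estimates and measured must have equal length")
  }
  ei <- ncep_index(estimates)
  mi <- ncep_index(measured)
  status <- factor(ifelse(ei == mi, "concordant",
                          ifelse(ei < mi, "under", "over")),
                   levels = c("concordant", "under", "over"))
  out <- data.frame(estimate = estimates, measured = measured,
                    est_cat = ncep_category(estimates),
                    meas_cat = ncep_category(measured),
                    status = status)
  if (!is.null(id)) out <- cbind(id = id, out)
  out
}

#' Clopper-Pearson exact confidence interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)` (or a 2-column matrix for vector
#'   input).
#' @examples
#' clopper_pearson(8, 10)  # approximately (0.444, 0.975)
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (any(x < 0) || any(n < 1) || any(x > n)) {
    stop_validation("need 0 <= x <= n with n >= 1")
  }
  a <- 1 - conf
  lo <- ifelse(x == 0, 0, qbeta(a / 2, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - a / 2, x + 1, n - x))
  if (length(x) == 1 && length(n) == 1) c(lo = lo, hi = hi)
  else cbind(lo = lo, hi = hi)
}

#' Concordance summary with exact confidence intervals
#'
#' Counts concordant / under / over per group and attaches the
#' concordance rate with its Clopper-Pearson interval. Grouping mirrors
#' the standard report shapes: overall, by TG stratum, or by estimated
#' LDL-C category.
#'
#' @param results A classification data.frame from [classify()].
#' @param by `"none"`, `"tg"` or `"est_category"`.
#' @param tg Triglyceride values aligned with `results` (required for
#'   `by = "tg"`).
#' @param tg_breaks Interior TG cut points for grouping (default the six
#'   standard strata).
#' @param conf Confidence level.
#' @return A data.frame with one row per group: `group`, `n`,
#'   `concordant`, `under`, `over`, `rate`, `ci_lo`, `ci_hi`. Empty groups
#'   are omitted with a warning.
#' @export
concordance_summary <- function(results, by = c("none", "tg", "est_category"),
                                tg = NULL, tg_breaks = c(50, 100, 150, 200, 300),
                                conf = 0.95) {
  by <- match.arg(by)
  if (nrow(results) == 0) stop_input("results is empty")
  group <- switch(by,
    none = factor(rep("overall", nrow(results))),
    tg = {
      if (is.null(tg)) stop_input("by = 'tg' requires the tg vector")
      if (length(tg) != nrow(results)) {
        stop_input("tg must align with results rows")
      }
      lab <- tg_band_labels(tg_breaks)
      factor(lab[findInterval(tg, tg_breaks) + 1L], levels = lab)
    },
    est_category = results$est_cat
  )
  empty <- setdiff(levels(group), unique(as.character(group)))
  if (length(empty)) {
    warning(sprintf("omitting empty groups: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  groups <- levels(group)[levels(group) %in% unique(as.character(group))]
  rows <- lapply(groups, function(g) {
    st <- results$status[group == g]
    n <- length(st)
    k <- sum(st == "concordant")
    ci <- clopper_pearson(k, n, conf)
    data.frame(group = g, n = n, concordant = k,
               under = sum(st == "under"), over = sum(st == "over"),
               rate = k / n, ci_lo = ci[[1]], ci_hi = ci[[2]])
  })
  do.call(rbind, rows)
}

tg_band_labels <- function(breaks) {
  lo <- c(0, breaks); hi <- c(breaks, Inf)
  ifelse(is.infinite(hi), paste0(">=", lo),
         ifelse(lo == 0, paste0("<", hi), paste0(lo, "-", hi)))
}

#' Exact McNemar test from the two discordant counts
#'
#' Two-sided exact binomial test for correlated proportions:
#' `p = min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`.
#'
#' @param b,c The two discordant cross-counts (method A right / B wrong,
#'   and vice versa).
#' @return The p-value. When `b + c = 0` the test is degenerate: 1 is
#'   returned with attribute `degenerate = TRUE`.
#' @examples
#' mcnemar_exact(14, 21)  # 0.311
#' mcnemar_exact(1, 9)    # 0.021
#' @export
mcnemar_exact <- function(b, c) {
  if (length(b) != 1 || length(c) != 1 || b < 0 || c < 0 ||
      b != round(b) || c != round(c)) {
    stop_validation("b and c must be single non-negative integer counts")
  }
  n <- b + c
  if (n == 0) return(structure(1.0, degenerate = TRUE))
  min(1, 2 * pbinom(min(b, c), n, 0.5))
}

#' Treatment-category reclassification between two estimators
#'
#' Cross-tabulates, within each category block assigned by the reference
#' estimator, whether each estimator's category is correct (equals the
#' directly measured category). The two discordant cells feed an exact
#' McNemar test per block and overall; upward / downward moves count
#' individuals whose alternative category is above / below the reference
#' one.
#'
#' @param ref_estimates,alt_estimates Numeric LDL-C estimates (reference,
#'   e.g. Friedewald; and alternative), aligned with `measured`.
#' @param measured Directly measured LDL-C.
#' @return A data.frame of class `reclass_table`, one row per reference
#'   category plus `overall`: block `n`, the four cross-counts
#'   `ref_correct_alt_correct` (`cc`), `cc_ci` (`ref` correct only),
#'   `ic` (`alt` correct only), `ii`, their percentages of block `n`,
#'   `up`/`down` move counts, and `p_value`.
#' @export
reclassification <- function(ref_estimates, alt_estimates, measured) {
  n <- length(measured)
  if (length(ref_estimates) != n || length(alt_estimates) != n) {
    stop_input("ref_estimates, alt_estimates and measured must align")
  }
  ri <- ncep_index(ref_estimates)
  ai <- ncep_index(alt_estimates)
  mi <- ncep_index(measured)
  ref_ok <- ri == mi
  alt_ok <- ai == mi
  block <- factor(NCEP_LABELS[ri + 1L], levels = NCEP_LABELS)
  one_block <- function(sel, label) {
    data.frame(
      block = label, n = sum(sel),
      cc = sum(sel & ref_ok & alt_ok),
      ci = sum(sel & ref_ok & !alt_ok),
      ic = sum(sel & !ref_ok & alt_ok),
      ii = sum(sel & !ref_ok & !alt_ok),
      up = sum(sel & ai > ri), down = sum(sel & ai < ri),
      p_value = as.numeric(mcnemar_exact(sum(sel & ref_ok & !alt_ok),
                                         sum(sel & !ref_ok & alt_ok)))
    )
  }
  rows <- lapply(NCEP_LABELS, function(lb) one_block(block == lb, lb))
  rows <- c(rows, list(one_block(rep(TRUE, n), "overall")))
  out <- do.call(rbind, rows)
  out$block <- factor(out$block, levels = c(NCEP_LABELS, "overall"))
  for (col in c("cc", "ci", "ic", "ii")) {
    out[[paste0("pct_", col)]] <- ifelse(out$n > 0, pct(out[[col]] / out$n), NA)
  }
  class(out) <- c("reclass_table", "data.frame")
  out
}

#' Bland-Altman agreement summary
#'
#' Mean bias of `estimates - measured` with 95% limits of agreement
#' `bias +/- 1.96 * sd` (sample standard deviation of the differences;
#' the 1.96 constant is used as printed in method-comparison practice,
#' not a t quantile).
#'
#' @param estimates,measured Aligned numeric LDL-C vectors, mg/dL.
#' @param subset Optional logical vector restricting the analysis (e.g. a
#'   TG subgroup).
#' @return A list: `n`, `bias`, `sd`, `loa_lo`, `loa_hi`.
#' @export
bland_altman <- function(estimates, measured, subset = NULL) {
  if (length(estimates) != length(measured)) {
    stop_input("estimates and measured must have equal length")
  }
  if (!is.null(subset)) {
    estimates <- estimates[subset]
    measured <- measured[subset]
  }
  if (length(estimates) < 2) {
    stop_input("Bland-Altman analysis needs at least 2 paired values")
  }
  d <- estimates - measured
  bias <- mean(d)
  s <- sd(d)
  list(n = length(d), bias = bias, sd = s,
       loa_lo = bias - 1.96 * s, loa_hi = bias + 1.96 * s)
}

#' Fit and error metrics against measured LDL-C
#'
#' `mae = mean |e - m|`, `mse = mean (e - m)^2`,
#' `mre = 100 * mean((e - m) / m)` (signed, percent; rows with `m = 0`
#' are excluded with a warning), and prediction
#' `r2 = 1 - sum((e - m)^2) / sum((m - mean(m))^2)` with the measured
#' values as truth (can be negative).
#'
#' @param estimates,measured Aligned numeric LDL-C vectors, mg/dL.
#' @return A list: `r2`, `mre` (percent), `mae` (mg/dL), `mse` (mg/dL^2).
#' @export
fit_metrics <- function(estimates, measured) {
  if (length(estimates) != length(measured) || length(measured) < 2) {
    stop_input("need aligned vectors with n >= 2")
  }
  d <- estimates - measured
  zero <- measured == 0
  if (any(zero)) {
    warning(sprintf("excluding %d rows with measured = 0 from MRE", sum(zero)),
            call. = FALSE)
  }
  list(
    r2 = 1 - sum(d^2) / sum((measured - mean(measured))^2),
    mre = 100 * mean(d[!zero] / measured[!zero]),
    mae = mean(abs(d)),
    mse = mean(d^2)
  )
}
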