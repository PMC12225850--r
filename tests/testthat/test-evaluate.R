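test_that("classification labels follow the category comparison", {
  cl <- classify(c(65, 80, 80), c(80, 80, 65))
  expect_equal(as.character(cl$status), c("under", "concordant", "over"))

  # equal values are concordant anywhere on the scale
  x <- c(-5, 69.9, 100, 189.99, 400)
  expect_true(all(classify(x, x)$status == "concordant"))

  set.seed(47)
  est <- runif(500, -20, 260)
  meas <- runif(500, 0, 260)
  cl <- classify(est, meas)
  oracle <- sign(ncep_index(est) - ncep_index(meas))
  expect_equal(as.character(cl$status),
               c("concordant", "over", "under")[match(oracle, c(0, 1, -1))])
})

test_that("classification pairs estimate records with measured rows by id", {
  coh <- random_panels(30, seed = 51)
  est <- estimate_friedewald(coh)
  shuffled <- coh[sample(nrow(coh)), c("id", "ldl_d")]
  cl <- classify(est, shuffled)
  expect_equal(cl$measured, coh$ldl_d)
  bad <- shuffled; bad$id[1] <- "nope"
  expect_error(classify(est, bad), "pair", class = "ldlstrat_input_error")
})

test_that("concordance summaries carry exact Clopper-Pearson intervals", {
  cl <- classify(c(rep(80, 8), 120, 120), rep(80, 10))  # 8 of 10 concordant
  s <- concordance_summary(cl)
  expect_equal(s$rate, 0.8)
  expect_equal(s$ci_lo, qbeta(0.025, 8, 3), tolerance = 1e-12)
  expect_equal(s$ci_hi, qbeta(0.975, 9, 2), tolerance = 1e-12)
  expect_equal(round(c(s$ci_lo, s$ci_hi), 3), c(0.444, 0.975))

  expect_equal(unname(clopper_pearson(0, 7)[1]), 0)
  expect_equal(unname(clopper_pearson(7, 7)[2]), 1)
})

test_that("grouped concordance reproduces per-stratum rates", {
  coh <- generate_cohort(synth_preset("population1", n = 3000, seed = 53))
  est <- estimate_friedewald(coh)
  cl <- classify(est$estimate, coh$ldl_d)
  s <- suppressWarnings(concordance_summary(cl, by = "tg", tg = coh$tg))
  expect_equal(sum(s$n), 3000)
  expect_true(all(s$concordant + s$under + s$over == s$n))
  expect_true(all(s$ci_lo <= s$rate & s$rate <= s$ci_hi))
  s2 <- suppressWarnings(concordance_summary(cl, by = "est_category"))
  expect_equal(sum(s2$n), 3000)
})

test_that("exact McNemar agrees with brute-force binomial enumeration", {
  expect_equal(round(mcnemar_exact(14, 21), 3), 0.311)
  expect_equal(round(mcnemar_exact(1, 9), 3), 0.021)
  expect_equal(mcnemar_exact(7, 7), 1)
  degen <- mcnemar_exact(0, 0)
  expect_equal(as.numeric(degen), 1)
  expect_true(attr(degen, "degenerate"))
  expect_error(mcnemar_exact(-1, 2), class = "ldlstrat_validation_error")

  for (n in 1:30) {
    for (b in 0:n) {
      c_ <- n - b
      pmf <- choose(n, 0:n) / 2^n          # independent pmf enumeration
      brute <- min(1, 2 * sum(pmf[seq_len(min(b, c_) + 1)]))
      expect_equal(mcnemar_exact(b, c_), brute, tolerance = 1e-12)
      expect_equal(mcnemar_exact(b, c_), mcnemar_exact(c_, b))
    }
  }
})

test_that("reclassification cross-counts match a per-row oracle", {
  # toy cohort: reference misclassifies 2, the alternative fixes both
  meas <- c(80, 80, 80, 80, 80, 80)
  ref <- c(80, 85, 90, 95, 65, 69)   # last two under-estimated
  alt <- rep(80, 6)
  rt <- reclassification(ref, alt, meas)
  b70 <- rt[rt$block == "<70", ]
  b79 <- rt[rt$block == "70-99", ]
  expect_equal(b70$n, 2)
  expect_equal(unlist(b70[, c("cc", "ci", "ic", "ii")]),
               c(cc = 0, ci = 0, ic = 2, ii = 0))
  expect_equal(b70$up, 2)
  expect_equal(unlist(b79[, c("cc", "ci", "ic", "ii")]),
               c(cc = 4, ci = 0, ic = 0, ii = 0))
  overall <- rt[rt$block == "overall", ]
  expect_equal(overall$ic, 2)

  # block percentages partition
  expect_true(all(abs(rowSums(rt[rt$n > 0, c("pct_cc", "pct_ci", "pct_ic", "pct_ii")]) -
                        100) <= 0.2))

  # synthetic cohort vs independent tabulation
  coh <- generate_cohort(synth_preset("combined", n = 3000, seed = 59))
  f <- estimate_friedewald(coh)$estimate
  opt <- read_ratio_table(system.file("extdata", "ratio_table_six_tg_optimal.json",
                                      package = "ldlstrat"))
  a <- estimate_martin_hopkins(coh, opt)$estimate
  rt2 <- reclassification(f, a, coh$ldl_d)
  fi <- ncep_index(f); ai <- ncep_index(a); mi <- ncep_index(coh$ldl_d)
  for (k in 0:5) {
    sel <- fi == k
    row <- rt2[as.integer(rt2$block) == k + 1, ]
    expect_equal(row$n, sum(sel))
    expect_equal(row$cc, sum(sel & fi == mi & ai == mi))
    expect_equal(row$ci, sum(sel & fi == mi & ai != mi))
    expect_equal(row$ic, sum(sel & fi != mi & ai == mi))
    expect_equal(row$ii, sum(sel & fi != mi & ai != mi))
    expect_equal(row$p_value, mcnemar_exact(row$ci, row$ic), tolerance = 1e-12)
  }
})

test_that("Bland-Altman recovers known bias and limits of agreement", {
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3))[c("bias", "loa_lo", "loa_hi")],
               list(bias = 0, loa_lo = 0, loa_hi = 0))
  ba10 <- bland_altman(c(11, 12, 13), c(1, 2, 3))
  expect_equal(ba10$bias, 10)
  expect_equal(c(ba10$loa_lo, ba10$loa_hi), c(10, 10))
  expect_error(bland_altman(1, 1), class = "ldlstrat_input_error")

  set.seed(61)
  meas <- runif(10000, 60, 200)
  est <- meas + rnorm(10000, -5, 8)
  ba <- bland_altman(est, meas)
  expect_lt(abs(ba$bias - (-5)), 0.3)
  expect_lt(abs(ba$loa_lo - (-5 - 1.96 * 8)), 0.5)
  expect_lt(abs(ba$loa_hi - (-5 + 1.96 * 8)), 0.5)
})

test_that("fit metrics match brute-force summation", {
  m <- fit_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m, list(r2 = 1, mre = 0, mae = 0, mse = 0))

  mk <- fit_metrics(c(11, 12, 13), c(1, 2, 3))
  expect_equal(mk$mae, 10)
  expect_equal(mk$mse, 100)

  set.seed(67)
  meas <- runif(200, 50, 200)
  est <- meas + rnorm(200, 0, 10)
  got <- fit_metrics(est, meas)
  d <- est - meas
  expect_equal(got$mae, sum(abs(d)) / 200)
  expect_equal(got$mse, sum(d^2) / 200)
  expect_equal(got$mre, 100 * sum(d / meas) / 200)
  expect_equal(got$r2, 1 - sum(d^2) / sum((meas - mean(meas))^2))
})
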