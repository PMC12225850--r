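---
title: "Stratified TG/VLDL-C ratios for LDL cholesterol estimation: models, derivation, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified TG/VLDL-C ratios for LDL cholesterol estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldlstrat)
```

## The estimation problem

LDL cholesterol is the primary treatment target in cardiovascular
prevention, but most laboratories do not measure it directly for every
panel. Instead it is estimated from total cholesterol (TC), HDL-C and
triglycerides (TG), all in mg/dL. Both estimators in this package share
one algebraic form:

    LDL-C = non-HDL-C - TG / AF,    non-HDL-C = TC - HDL-C

where `TG / AF` estimates VLDL cholesterol. The Friedewald formula fixes
the adjustable factor at `AF = 5`, i.e. it assumes every individual's
TG/VLDL-C ratio is 5. That assumption degrades at elevated TG: the true
ratio rises with TG, so dividing by 5 over-estimates VLDL-C and
under-estimates LDL-C, pushing high-TG individuals into treatment bands
below their measured one. The Martin–Hopkins approach replaces the
constant with a strata-specific AF looked up by TG and non-HDL-C level.

This package implements that framework end to end: the estimators, the
stratification schemes, two ways of deriving the per-stratum AF from a
cohort with directly measured LDL-C, and the evaluation battery used to
compare estimators against direct measurement. Everything operates on
fasting panels with TG < 400 mg/dL (the `filter_eligible()` bound);
mmol/L is deliberately unsupported because every formula here is stated
in mg/dL.

## Median versus optimal adjustable factors

Given a derivation cohort with directly measured LDL-C (`ldl_d`), each
individual's observed ratio is `tg / vldl_c` with
`vldl_c = non_hdl - ldl_d`.

**Median tables** (`median_ratio_table()`) take the per-cell sample
median of the observed ratios. Confidence intervals are distribution
free: the interval between the `l`-th and `(n+1-l)`-th order statistics,
with `l` the largest symmetric rank whose exact binomial coverage
`P(l <= B <= n-l)`, `B ~ Binomial(n, 1/2)`, is at least 95%. Because
coverage is a step function of `l`, the achieved confidence level (ACL)
generally exceeds the nominal one and is reported alongside each
interval. For `n < 6` no symmetric pair reaches 95%; the interval then
widens to the sample extremes and the (sub-nominal) achieved coverage is
reported honestly rather than hidden. Even-sized cells use the
conventional mean of the two central order statistics as the median.

**Optimal tables** (`optimal_ratio_table()`) ask a different question:
not "what is the typical ratio?" but "which single AF, applied to this
whole cell, classifies the most individuals into their measured
NCEP–ATP III band?" The search is exhaustive over the grid 1.0–10.0 in
0.1 steps (91 candidates, generated as scaled integers so each value is
exactly the number it prints as). The objective needs only non-HDL-C, TG
and the measured category, so individuals whose observed ratio is
undefined (`vldl_c <= 0`) still contribute to it; they are excluded only
from median derivation. Ties at the maximum break deterministically to
the lowest grid value and are flagged in the table's `tie` column.

The two derivations differ most when the within-cell ratio distribution
is skewed relative to the category boundaries: the median minimizes a
within-cell distance to the observed ratios, while the optimum directly
maximizes the classification objective the guideline cares about.
`discordance_curve()` exposes the underlying trade-off: because the
estimate is strictly increasing in AF (for TG > 0), the
under-classification count is non-increasing and the over-classification
count non-decreasing along the grid — the concordance peak sits where
the two error types cross over.

## Categories, classification, and numerical conventions

The six NCEP–ATP III bands (`<70`, `70–99`, `100–129`, `130–159`,
`160–189`, `>=190` mg/dL) are half-open `[lo, hi)` intervals applied to
*unrounded* values; treating "70–99 / 100–129" as a partition at exactly
100 is the only reading that makes the labels exhaustive on a continuous
scale. Estimates are never clipped: a negative estimate (possible at
high TG with low non-HDL-C) classifies as `<70` and carries a `negative`
flag so downstream reports can surface it.

Other fixed numerical choices:

* Stratification intervals are half-open everywhere, consistent with the
  category bands; TG outside `[0, 400)` raises an error rather than
  clamping, mirroring the eligibility exclusion.
* Derived AF values are stored at the 0.1 grid resolution, written to
  ratio-table files as one-decimal strings so write/read round trips are
  bit-identical and no `0.30000000000000004`-style labels can appear.
* Reported percentages round half-away-from-zero to one decimal
  (`pct()`), the convention of printed clinical tables.
* Bland–Altman limits of agreement use the conventional 1.96 constant,
  not a t quantile; the SD is the sample standard deviation of the
  differences.
* The McNemar test for paired concordance comparisons is the exact
  two-sided binomial version: `p = min(1, 2 * P(X <= min(b, c)))`,
  `X ~ Binomial(b + c, 1/2)`. Tail doubling (rather than a mid-p
  variant) is the convention that reproduces the worked examples this
  package tests against.
* The mean relative error is signed (`100 * mean((est - meas) / meas)`),
  and R² is the prediction form `1 - SSE/SST` with measured LDL-C as
  truth — it ranks estimators against measurement and can be negative.
  Both definitions are open conventions in the literature; these are the
  ones consistent with the error tables this package mirrors.

## Stratification schemes

`builtin_scheme()` ships four schemes: the six standard TG bands
(`six_tg`); the 12-cell combined scheme splitting each TG band at
non-HDL-C 130 mg/dL (`twelve_combined`); a 12-band TG-only refinement
(`twelve_tg`); and a 28-cell combined scheme (`twentyeight_combined`).
The latter two load from packaged scheme files whose boundary values are
*synthetic*: package-chosen (each standard TG band split at its midpoint
for `twelve_tg`; 3–4 non-HDL-C cuts per TG band, denser where screening
populations are denser, for the 28-cell scheme) and deliberately stored
as data files rather than code so users can substitute their own
boundaries — including externally published 10-cell or 180-cell tables —
without touching the package. `census()` reports per-cell occupancy
against the conventional 100-sample floor before any derivation is
trusted.

## The synthetic cohort generator

`generate_cohort()` exists so the whole pipeline is testable without
access to survey data. What it emulates, and how:

* **Marginals.** TG, non-HDL-C and HDL-C are lognormal, parameterized by
  median and IQR (sigma from the IQR ratio via normal quantiles), the
  right-skewed shape typical of lipid panels whose summaries are
  published as median (IQR). When a TG truncation range is set, the
  untruncated parameters are re-calibrated by a deterministic
  Nelder–Mead fit so the *truncated* distribution hits the target
  median/IQR.
* **Dependence.** TG and non-HDL-C are coupled by a Gaussian copula at
  Spearman rank correlation 0.35 by default — an arbitrary but
  documented value chosen once so that all 12 combined cells stay
  populated; real survey dependence is unknown here.
* **Ratio structure.** The true TG/VLDL-C ratio surface is log-linear,
  `r = 4.0 + 1.5 log(TG) - 1.2 log(non-HDL-C)`, multiplied by lognormal
  noise (sigma 0.25) and clamped to (1, 12). The coefficients were
  chosen once to reproduce the two qualitative facts the derivation
  tables document — ratios rise with TG across strata and fall with
  non-HDL-C within a stratum — at realistic magnitudes (cell medians
  spanning roughly 3 to 7). Alternatively a `ratio_table` can supply a
  cell-wise constant truth surface, which is how the parameter-recovery
  tests work.
* **Consistency.** `vldl = tg / r`, `ldl_d = non_hdl - vldl`,
  `tc = non_hdl + hdl`, so every generated panel is internally exact;
  rows violating positivity are rejection-resampled (not clamped, which
  would distort the marginals) with a retry budget of 100× the requested
  size, after which generation aborts as infeasible.

The presets mirror the two study populations this design emulates:
`population1` (general screening; TG median 102, IQR 69–150),
`population2` (TG restricted to 200–399; median 247, IQR 219–291), and
`combined`, their 11,930 : 6,392 mixture used for ratio derivation.

What the generator does **not** emulate: age/sex structure, assay
measurement error (the generated `ldl_d` is exact given the latent
ratio), survey weights, and any real-world dependence between the ratio
noise and the marginals. Passing tests on synthetic cohorts therefore
demonstrates that the derivation and evaluation machinery is correct and
that the method recovers known structure — not that any particular
published ratio value generalizes to other populations or assays.

## Problem sizes and reproducibility

The shipped tests derive tables on synthetic cohorts of 6,000–20,000
individuals (seeded, deterministic to the byte), which populates the
dense cells of the 12-cell scheme with 2,000+ members — the scale at
which the recovery guarantee (optimal AF within 0.2 of a grid-valued
truth) is asserted. Sparse cells (e.g. TG < 50 with non-HDL-C >= 130)
fall below that and are deliberately left outside the guarantee, exactly
as real low-occupancy strata would be. The exact-inference components
(median CI ranks, Clopper–Pearson, McNemar) are cross-checked against
brute-force enumeration oracles at small n, where exhaustive computation
is feasible.

## Known limitations

* Optimal AFs are in-sample optimizers; with small cells they can
  overfit, which is why occupancy floors and the tie flag are surfaced
  rather than hidden. Cross-validated scheme selection and smoothing of
  the AF surface across neighboring cells are out of scope.
* Ratio values derived from one population and assay do not transfer
  automatically; the file formats make tables swappable precisely so
  users can re-derive locally.
* Regression-style LDL-C equations (multi-coefficient fits in the
  Sampson family) are not implemented; the fixed/lookup interfaces leave
  room for them but their coefficients are not part of this package.
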