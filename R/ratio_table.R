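# Ratio tables: a per-cell adjustable factor (AF) — the strata-specific
# TG/VLDL-C ratio an estimator divides TG by — plus derivation metadata
# (sample size, confidence interval, achieved confidence level, tie flag).

#' Construct a ratio table
#'
#' @param scheme A `strat_scheme`.
#' @param statistic How the AFs were obtained: `"fixed"` (e.g. the
#'   Friedewald constant 5), `"median"`, or `"optimal"`. Derived tables
#'   (`median`/`optimal`) must keep every AF in `[1, 10]` (the search
#'   grid); fixed tables only require positivity.
#' @param af Numeric vector of adjustable factors, one per cell in
#'   [scheme_cells()] order.
#' @param n,ci_lo,ci_hi,acl,tie Optional per-cell metadata: sample size,
#'   confidence bounds (ratio units), achieved confidence level
#'   (proportion), and whether the grid argmax was tied.
#' @return An object of class `ratio_table`.
#' @export
ratio_table <- function(scheme, statistic, af,
                        n = NA_integer_, ci_lo = NA_real_, ci_hi = NA_real_,
                        acl = NA_real_, tie = NA) {
  stopifnot(inherits(scheme, "strat_scheme"))
  statistic <- match.arg(statistic, c("fixed", "median", "optimal"))
  cells <- scheme_cells(scheme)
  k <- nrow(cells)
  if (length(af) != k) {
    stop_config(sprintf("af must have one value per cell (%d), got %d",
                        k, length(af)))
  }
  if (any(!is.finite(af)) || any(af <= 0)) {
    stop_schema("every af must be a positive finite number")
  }
  if (statistic != "fixed" && (any(af < 1) || any(af > 10))) {
    stop_schema("derived (median/optimal) tables require af in [1, 10]")
  }
  rec <- function(x) rep_len(x, k)
  cells$af <- as.numeric(af)
  cells$n <- rec(n)
  cells$ci_lo <- rec(ci_lo)
  cells$ci_hi <- rec(ci_hi)
  cells$acl <- rec(acl)
  cells$tie <- rec(tie)
  structure(list(scheme = scheme, statistic = statistic, cells = cells),
            class = "ratio_table")
}

#' Fixed-ratio table (every cell shares one AF)
#'
#' With `af = 5` this is the Friedewald assumption expressed as a lookup
#' table, which makes the Friedewald formula a special case of the
#' stratified estimator.
#'
#' @param scheme A `strat_scheme`.
#' @param af The single adjustable factor (default 5).
#' @return A `ratio_table` with `statistic = "fixed"`.
#' @export
fixed_ratio_table <- function(scheme, af = 5) {
  ratio_table(scheme, "fixed", rep(af, n_cells(scheme)))
}

#' Look up per-individual adjustable factors
#'
#' @param table A `ratio_table`.
#' @param tg,nonhdl Panel values, mg/dL.
#' @return Numeric vector of AFs.
#' @export
lookup_af <- function(table, tg, nonhdl = NULL) {
  stopifnot(inherits(table, "ratio_table"))
  if (any(table$cells$af <= 0)) stop_schema("ratio table contains af <= 0")
  table$cells$af[assign_cell(table$scheme, tg, nonhdl)]
}

#' Method label in the subscript naming convention
#'
#' Builds labels like `LDL-C_KM-12`, `LDL-C_KO-28` or `LDL-C_KM-6-TG`:
#' `KM`/`KO` for median/optimal tables derived from the data at hand,
#' `M` for externally published median tables, with the cell count and a
#' `-TG` suffix for TG-only stratifications.
#'
#' @param table A `ratio_table`.
#' @param source `"K"` for locally derived tables, `"M"` for external ones.
#' @return A single string.
#' @export
method_label <- function(table, source = c("K", "M")) {
  stopifnot(inherits(table, "ratio_table"))
  source <- match.arg(source)
  stat_tag <- switch(table$statistic, fixed = "F", median = "M", optimal = "O")
  if (table$statistic == "fixed") return("LDL-C_F")
  prefix <- if (source == "K") paste0("K", stat_tag) else "M"
  tg_only <- all(vapply(table$scheme$nonhdl_breaks, length, 1L) == 0)
  paste0("LDL-C_", prefix, "-", n_cells(table$scheme),
         if (tg_only) "-TG" else "")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("<ratio_table: %s, %d cells over scheme '%s'>\n",
              x$statistic, nrow(x$cells), x$scheme$name))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

# one fractional digit: the grid resolution at which derived AFs live
format_af <- function(af) sprintf("%.1f", af)

#' Read / write a ratio-table file
#'
#' The container is JSON: `scheme` (as in [write_scheme()]), `statistic`,
#' and `cells`, a list of `{tg_lo, tg_hi, nonhdl_lo, nonhdl_hi, af, n,
#' ci_lo, ci_hi, acl}` with open upper bounds encoded as `null`. Derived
#' tables carry `af` as one-decimal strings (the grid resolution), so a
#' write/read round trip reproduces them bit-identically.
#'
#' @param path File path.
#' @return For `read_ratio_table`, a `ratio_table`.
#' @export
read_ratio_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "ratio-table")) {
    stop_schema("not a ratio-table file (missing format tag)")
  }
  sch <- obj$scheme
  nb <- lapply(sch$nonhdl_breaks_per_tg, function(b) as.numeric(unlist(b)))
  scheme <- strat_scheme(sch$name, as.numeric(unlist(sch$tg_breaks)),
                         nonhdl_breaks = nb,
                         tg_range = as.numeric(unlist(sch$tg_range)))
  cells <- scheme_cells(scheme)
  got <- obj$cells
  if (length(got) != nrow(cells)) {
    stop_schema(sprintf(
      "cell list does not tile the scheme: expected %d cells, found %d (gap or overlap)",
      nrow(cells), length(got)))
  }
  num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)
  for (i in seq_along(got)) {
    g <- got[[i]]
    same <- isTRUE(all.equal(
      c(num_or(g$tg_lo, 0), num_or(g$tg_hi, Inf),
        num_or(g$nonhdl_lo, 0), num_or(g$nonhdl_hi, Inf)),
      c(cells$tg_lo[i], cells$tg_hi[i], cells$nonhdl_lo[i], cells$nonhdl_hi[i])
    ))
    if (!same) {
      stop_schema(sprintf(
        "cell %d intervals do not match the scheme (gap, overlap or misordering)", i))
    }
  }
  af <- vapply(got, function(g) as.numeric(g$af), 1.0)
  if (any(!is.finite(af)) || any(af <= 0)) {
    stop_schema("af values must be positive finite numbers")
  }
  ratio_table(
    scheme, obj$statistic, af,
    n = vapply(got, function(g) num_or(g$n, NA_real_), 1.0),
    ci_lo = vapply(got, function(g) num_or(g$ci_lo, NA_real_), 1.0),
    ci_hi = vapply(got, function(g) num_or(g$ci_hi, NA_real_), 1.0),
    acl = vapply(got, function(g) num_or(g$acl, NA_real_), 1.0),
    tie = vapply(got, function(g) if (is.null(g$tie)) NA else as.logical(g$tie), TRUE)
  )
}

#' @rdname read_ratio_table
#' @param table A `ratio_table`.
#' @export
write_ratio_table <- function(table, path) {
  stopifnot(inherits(table, "ratio_table"))
  derived <- table$statistic != "fixed"
  cl <- table$cells
  cells <- lapply(seq_len(nrow(cl)), function(i) {
    enc <- function(x) if (is.na(x)) NULL else if (is.infinite(x)) NULL else x
    list(
      tg_lo = cl$tg_lo[i], tg_hi = enc(cl$tg_hi[i]),
      nonhdl_lo = cl$nonhdl_lo[i], nonhdl_hi = enc(cl$nonhdl_hi[i]),
      af = if (derived) format_af(cl$af[i]) else cl$af[i],
      n = enc(cl$n[i]), ci_lo = enc(cl$ci_lo[i]), ci_hi = enc(cl$ci_hi[i]),
      acl = enc(cl$acl[i]),
      tie = if (is.na(cl$tie[i])) NULL else cl$tie[i]
    )
  })
  obj <- list(
    format = "ratio-table",
    scheme = list(
      name = table$scheme$name,
      tg_range = table$scheme$tg_range,
      tg_breaks = table$scheme$tg_breaks,
      nonhdl_breaks_per_tg = table$scheme$nonhdl_breaks
    ),
    statistic = table$statistic,
    cells = cells
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
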