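# Stratification schemes over triglycerides and (optionally) non-HDL-C.
#
# A scheme partitions the eligible TG range [0, 400) mg/dL into half-open
# intervals [lo, hi); each TG interval may carry its own ascending list of
# non-HDL-C cut points, splitting it into half-open non-HDL-C sub-cells
# (the last sub-cell is open above). Every eligible panel maps to exactly
# one cell.

#' Construct a stratification scheme
#'
#' @param name Scheme name (free text).
#' @param tg_breaks Ascending interior TG cut points, mg/dL, strictly inside
#'   `tg_range`; the implied intervals are half-open `[lo, hi)`.
#' @param nonhdl_breaks Either `NULL` (TG-only scheme) or a list with one
#'   ascending (possibly empty) numeric vector of non-HDL-C cut points per
#'   TG interval.
#' @param tg_range Covered TG range, default `c(0, 400)`; panels outside it
#'   raise an error rather than being clamped.
#' @return An object of class `strat_scheme`.
#' @examples
#' strat_scheme("six_tg", c(50, 100, 150, 200, 300))
#' @export
strat_scheme <- function(name, tg_breaks, nonhdl_breaks = NULL,
                         tg_range = c(0, 400)) {
  if (!is.numeric(tg_breaks) || length(tg_breaks) < 1) {
    stop_config("tg_breaks must be a non-empty numeric vector")
  }
  if (is.unsorted(tg_breaks, strictly = TRUE)) {
    stop_config("tg_breaks must be strictly ascending")
  }
  if (min(tg_breaks) <= tg_range[1] || max(tg_breaks) >= tg_range[2]) {
    stop_config("tg_breaks must lie strictly inside tg_range")
  }
  n_tg <- length(tg_breaks) + 1L
  if (is.null(nonhdl_breaks)) {
    nonhdl_breaks <- rep(list(numeric(0)), n_tg)
  }
  if (!is.list(nonhdl_breaks) || length(nonhdl_breaks) != n_tg) {
    stop_config(sprintf(
      "nonhdl_breaks must be a list with one entry per TG interval (%d)", n_tg))
  }
  for (b in nonhdl_breaks) {
    if (length(b) && (!is.numeric(b) || is.unsorted(b, strictly = TRUE))) {
      stop_config("each nonhdl_breaks entry must be strictly ascending")
    }
  }
  structure(
    list(name = name, tg_range = as.numeric(tg_range),
         tg_breaks = as.numeric(tg_breaks),
         nonhdl_breaks = lapply(nonhdl_breaks, as.numeric)),
    class = "strat_scheme"
  )
}

#' Number of cells of a stratification scheme
#' @param scheme A `strat_scheme`.
#' @return Integer cell count.
#' @export
n_cells <- function(scheme) {
  stopifnot(inherits(scheme, "strat_scheme"))
  sum(vapply(scheme$nonhdl_breaks, length, 1L) + 1L)
}

# TG interval bounds as a data.frame(lo, hi)
tg_intervals <- function(scheme) {
  lo <- c(scheme$tg_range[1], scheme$tg_breaks)
  hi <- c(scheme$tg_breaks, scheme$tg_range[2])
  data.frame(lo = lo, hi = hi)
}

#' Enumerate the cells of a scheme
#'
#' @param scheme A `strat_scheme`.
#' @return A data.frame with one row per cell: `cell` (1-based id in
#'   lookup order), `tg_index`, `nonhdl_index`, and interval bounds
#'   `tg_lo, tg_hi, nonhdl_lo, nonhdl_hi` (`nonhdl_hi = Inf` for the open
#'   top sub-cell; `nonhdl_lo = 0` for the bottom one).
#' @export
scheme_cells <- function(scheme) {
  stopifnot(inherits(scheme, "strat_scheme"))
  ti <- tg_intervals(scheme)
  out <- do.call(rbind, lapply(seq_len(nrow(ti)), function(i) {
    b <- scheme$nonhdl_breaks[[i]]
    nh_lo <- c(0, b)
    nh_hi <- c(b, Inf)
    data.frame(tg_index = i, nonhdl_index = seq_along(nh_lo),
               tg_lo = ti$lo[i], tg_hi = ti$hi[i],
               nonhdl_lo = nh_lo, nonhdl_hi = nh_hi)
  }))
  out$cell <- seq_len(nrow(out))
  out[, c("cell", "tg_index", "nonhdl_index",
          "tg_lo", "tg_hi", "nonhdl_lo", "nonhdl_hi")]
}

#' @export
print.strat_scheme <- function(x, ...) {
  kind <- if (all(vapply(x$nonhdl_breaks, length, 1L) == 0)) "TG-only"
          else "TG x non-HDL-C"
  cat(sprintf("<strat_scheme '%s': %d cells (%s), TG [%g, %g) mg/dL>\n",
              x$name, n_cells(x), kind, x$tg_range[1], x$tg_range[2]))
  invisible(x)
}

#' Built-in stratification schemes
#'
#' `six_tg` is the six TG bands `<50, 50-99, 100-149, 150-199, 200-299,
#' 300-399`; `twelve_combined` splits each of the six at non-HDL-C
#' 130 mg/dL; `twelve_tg` is a 12-band TG-only refinement and
#' `twentyeight_combined` a 28-cell TG x non-HDL-C scheme, both loaded from
#' packaged scheme files with synthetic (package-chosen, user-swappable)
#' boundaries.
#'
#' @param name One of `"six_tg"`, `"twelve_tg"`, `"twelve_combined"`,
#'   `"twentyeight_combined"`.
#' @return A `strat_scheme`.
#' @export
builtin_scheme <- function(name) {
  six_breaks <- c(50, 100, 150, 200, 300)
  switch(name,
    six_tg = strat_scheme("six_tg", six_breaks),
    twelve_combined = strat_scheme(
      "twelve_combined", six_breaks,
      nonhdl_breaks = rep(list(130), 6)),
    twelve_tg = read_scheme(
      system.file("extdata", "scheme_twelve_tg_synthetic.json",
                  package = "ldlstrat", mustWork = TRUE)),
    twentyeight_combined = read_scheme(
      system.file("extdata", "scheme_twentyeight_combined_synthetic.json",
                  package = "ldlstrat", mustWork = TRUE)),
    stop_config(paste0(
      "unknown scheme '", name, "'; valid names: six_tg, twelve_tg, ",
      "twelve_combined, twentyeight_combined"))
  )
}

#' Assign panels to scheme cells
#'
#' Locates each individual's cell by half-open `[lo, hi)` comparison on TG,
#' then on non-HDL-C within the TG interval. Deterministic; TG values
#' outside the scheme's coverage raise an out-of-range error.
#'
#' @param scheme A `strat_scheme`.
#' @param tg Numeric vector of triglycerides, mg/dL.
#' @param nonhdl Numeric vector of non-HDL-C, mg/dL; required when the
#'   scheme stratifies on non-HDL-C.
#' @return Integer vector of 1-based cell ids (rows of [scheme_cells()]).
#' @export
assign_cell <- function(scheme, tg, nonhdl = NULL) {
  stopifnot(inherits(scheme, "strat_scheme"))
  if (any(!is.finite(tg))) stop_validation("tg contains non-finite values")
  if (any(tg < scheme$tg_range[1] | tg >= scheme$tg_range[2])) {
    stop_range(sprintf("tg outside scheme coverage [%g, %g)",
                       scheme$tg_range[1], scheme$tg_range[2]))
  }
  uses_nonhdl <- any(vapply(scheme$nonhdl_breaks, length, 1L) > 0)
  if (uses_nonhdl && is.null(nonhdl)) {
    stop_input("scheme stratifies on non-HDL-C; 'nonhdl' is required")
  }
  ti <- findInterval(tg, c(scheme$tg_range[1], scheme$tg_breaks))
  n_sub <- vapply(scheme$nonhdl_breaks, length, 1L) + 1L
  offset <- c(0L, cumsum(n_sub))[seq_along(n_sub)]
  if (!uses_nonhdl) {
    return(offset[ti] + 1L)
  }
  if (any(!is.finite(nonhdl))) stop_validation("nonhdl contains non-finite values")
  ni <- integer(length(tg))
  for (i in unique(ti)) {
    sel <- ti == i
    ni[sel] <- findInterval(nonhdl[sel], scheme$nonhdl_breaks[[i]]) + 1L
  }
  offset[ti] + ni
}

#' Per-cell occupancy census
#'
#' Counts cohort members per scheme cell and flags cells whose sample size
#' falls below `min_n`, the conventional floor for a stable ratio estimate.
#'
#' @param cohort A lipid cohort data.frame (derived columns added if absent).
#' @param scheme A `strat_scheme`.
#' @param min_n Minimum acceptable per-cell count (default 100).
#' @param warn Emit a warning listing under-populated cells.
#' @return [scheme_cells()] with columns `n` and `under_min` appended;
#'   attribute `min_n`.
#' @export
census <- function(cohort, scheme, min_n = 100, warn = TRUE) {
  if (nrow(cohort) == 0) stop_input("cohort is empty")
  cohort <- derive_panel(cohort)
  cells <- scheme_cells(scheme)
  id <- assign_cell(scheme, cohort$tg, cohort$non_hdl)
  cells$n <- tabulate(id, nbins = nrow(cells))
  cells$under_min <- cells$n < min_n
  attr(cells, "min_n") <- min_n
  if (warn && any(cells$under_min)) {
    warning(sprintf("%d of %d cells have fewer than %d samples",
                    sum(cells$under_min), nrow(cells), min_n),
            call. = FALSE)
  }
  cells
}

#' Read / write a stratification scheme file
#'
#' Schemes are stored in the same JSON container family as ratio tables:
#' `{"format": "strat-scheme", "name": ..., "tg_range": [lo, hi],
#' "tg_breaks": [...], "nonhdl_breaks_per_tg": [[...], ...]}`.
#'
#' @param path File path.
#' @return For `read_scheme`, a `strat_scheme`.
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "strat-scheme")) {
    stop_schema("not a strat-scheme file (missing format tag)")
  }
  nb <- obj$nonhdl_breaks_per_tg
  if (is.null(nb)) nb <- NULL
  else if (is.matrix(nb)) nb <- lapply(seq_len(nrow(nb)), function(i) nb[i, ])
  else nb <- lapply(nb, function(b) as.numeric(unlist(b)))
  strat_scheme(obj$name, obj$tg_breaks, nonhdl_breaks = nb,
               tg_range = obj$tg_range)
}

#' @rdname read_scheme
#' @param scheme A `strat_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "strat_scheme"))
  obj <- list(
    format = "strat-scheme",
    name = scheme$name,
    tg_range = scheme$tg_range,
    tg_breaks = scheme$tg_breaks,
    nonhdl_breaks_per_tg = scheme$nonhdl_breaks
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
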