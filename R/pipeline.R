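# End-to-end orchestration: simulate (or read) a cohort, filter, derive
# ratio tables, estimate, evaluate, reclassify; write every stage output
# as plain CSV/JSON plus a log of filter counts and the resolved
# configuration, for auditability.

#' Run the full estimation pipeline
#'
#' Stages: obtain a cohort (`preset` simulation or `cohort_csv`), apply
#' the TG eligibility filter, derive median and optimal ratio tables on
#' the configured scheme, compute the Friedewald and stratified estimates,
#' and write concordance-by-TG and reclassification reports. All outputs
#' are plain text (CSV + JSON ratio tables); a rerun with the same seed is
#' byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort_csv Optional path to a cohort CSV; otherwise a synthetic
#'   cohort is generated.
#' @param preset Synthetic preset name for simulation (default
#'   `"combined"`).
#' @param n Synthetic cohort size (default 5000).
#' @param seed RNG seed.
#' @param scheme A `strat_scheme` or builtin scheme name (default
#'   `"twelve_combined"`).
#' @param statistics Ratio statistics to derive, subset of
#'   `c("median", "optimal")`.
#' @param min_n Per-cell floor passed to the derivations.
#' @return Invisibly, a list with the derived tables, estimates, and
#'   report data.frames.
#' @export
run_pipeline <- function(out_dir, cohort_csv = NULL, preset = "combined",
                         n = 5000, seed = 1, scheme = "twelve_combined",
                         statistics = c("median", "optimal"), min_n = 100) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(scheme)) scheme <- builtin_scheme(scheme)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  if (is.null(cohort_csv)) {
    cohort <- generate_cohort(synth_preset(preset, n = n, seed = seed))
    note("simulated cohort: preset=%s n=%d seed=%d", preset, nrow(cohort), seed)
  } else {
    cohort <- read_cohort(cohort_csv)
    note("input cohort: %s (%d rows)", cohort_csv, nrow(cohort))
  }

  flt <- filter_eligible(cohort)
  note("eligibility filter: kept=%d excluded_missing=%d excluded_tg=%d",
       nrow(flt$cohort), flt$report$n[1], flt$report$n[2])
  cohort <- flt$cohort
  if (nrow(cohort) == 0) {
    stop_derivation("no eligible individuals remain after the TG filter")
  }
  write_cohort(cohort, file.path(out_dir, "cohort_eligible.csv"),
               derived = TRUE)
  d <- derive_panel(cohort)
  note("undefined TG/VLDL-C ratios (vldl_c <= 0): %d",
       attr(d, "n_undefined_ratio"))

  tables <- list()
  estimates <- list(`LDL-C_F` = estimate_friedewald(cohort))
  for (stat in statistics) {
    tab <- if (stat == "median") {
      suppressMessages(median_ratio_table(cohort, scheme, min_n = min_n))
    } else {
      suppressMessages(optimal_ratio_table(cohort, scheme, min_n = min_n))
    }
    lbl <- method_label(tab)
    tables[[lbl]] <- tab
    write_ratio_table(tab, file.path(
      out_dir, paste0("ratio_table_", stat, ".json")))
    estimates[[lbl]] <- estimate_martin_hopkins(cohort, tab)
    note("derived %s table (%d cells) -> %s", stat, n_cells(scheme), lbl)
  }

  conc_rows <- lapply(names(estimates), function(lbl) {
    cl <- classify(estimates[[lbl]]$estimate, cohort$ldl_d)
    s <- suppressWarnings(concordance_summary(cl, by = "tg", tg = cohort$tg))
    cbind(method = lbl, s)
  })
  conc <- do.call(rbind, conc_rows)
  write.csv(conc, file.path(out_dir, "concordance_by_tg.csv"),
            row.names = FALSE)

  reclass <- NULL
  if (length(tables)) {
    alt <- estimates[[length(estimates)]]
    reclass <- reclassification(estimates[["LDL-C_F"]]$estimate,
                                alt$estimate, cohort$ldl_d)
    write.csv(as.data.frame(reclass),
              file.path(out_dir, "reclassification.csv"), row.names = FALSE)
    note("reclassification report: LDL-C_F vs %s", alt$method[1])
  }

  config <- list(preset = if (is.null(cohort_csv)) preset else NULL,
                 cohort_csv = cohort_csv, n = n, seed = seed,
                 scheme = scheme$name, statistics = statistics,
                 min_n = min_n)
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(tables = tables, estimates = estimates,
                 concordance = conc, reclassification = reclass))
}
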