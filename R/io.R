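#' Read a patch table from CSV
#'
#' Expects a header with columns `id,x,y,diameter` (meters, decimal point)
#' and optionally `cohort`; missing `id` is assigned from the row order and a
#' missing `cohort` is classified from the diameter. Rows with malformed or
#' non-positive values are reported with their line numbers; containment and
#' global non-overlap are validated against `window`.
#'
#' @param path CSV file path.
#' @param window A [rect_window()].
#' @param thresholds Cohort boundaries for classification.
#' @return A validated patch table.
#' @export
read_patch_table <- function(path, window, thresholds = c(0.25, 0.50, 1.00, 2.00)) {
  # base-R reader: strtod parses doubles to the nearest representable value,
  # so a full-precision write/read round trip is bit-exact
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("x", "y", "diameter")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0(path, ": missing column(s): ", paste(missing, collapse = ", ")))
  }
  num <- purrr::map(raw[need], ~ suppressWarnings(as.numeric(.x)))
  bad <- !is.finite(num$x) | !is.finite(num$y) | !is.finite(num$diameter) |
    num$diameter <= 0
  if (any(bad)) {
    lines <- which(bad) + 1 # header is line 1
    abort(paste0(path, ": malformed or non-positive values at line(s): ",
                 paste(head(lines, 10), collapse = ", ")))
  }
  raw[need] <- num
  patch_table(raw, window, thresholds = thresholds)
}

#' Write a patch table to CSV
#'
#' Full-precision serialization so a write/read round trip preserves every
#' field bit-exactly.
#'
#' @param patches A patch table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patch_table <- function(patches, path) {
  out <- dplyr::mutate(
    patches,
    cohort = as.character(.data$cohort),
    # 17 significant digits round-trip IEEE doubles exactly
    dplyr::across(c("x", "y", "diameter"), ~ sprintf("%.17g", .x))
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' The YAML may set any argument of [analysis_config()] plus a `window`
#' entry `[x_min, y_min, x_max, y_max]`; unset keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A list: `config` ([analysis_config()]) and `window`
#'   ([rect_window()] or `NULL`).
#' @export
read_analysis_config <- function(path) {
  spec <- yaml::read_yaml(path)
  window <- if (!is.null(spec$window)) as_rect_window(unlist(spec$window))
  spec$window <- NULL
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(spec), known)
  if (length(unknown)) {
    abort(paste0(path, ": unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  list(config = do.call(analysis_config, spec), window = window)
}

#' Export pipeline results
#'
#' Writes the main tables of a [run_full_pipeline()] result into a directory:
#' the hypothesis report (JSON and markdown), the cohort summary, plot
#' statistics, the correlation matrix, and per-cohort summary-function /
#' interval CSVs. Every artifact records the root seed and simulation count.
#'
#' @param result A `recruitment_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = result$seed, n_sims = result$config$n_sims)
  jsonlite::write_json(
    list(meta = meta,
         report = result$report,
         corr1 = list(verdict = result$corr1$verdict, results = result$corr1$results),
         corr2 = result$corr2[c("verdict", "n_significant", "threshold")]),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  writeLines(report_markdown(result$report), file.path(dir, "report.md"))
  readr::write_csv(result$summary, file.path(dir, "pattern_summary.csv"))
  readr::write_csv(result$plot_stats, file.path(dir, "plot_stats.csv"))
  readr::write_csv(result$corr_matrix, file.path(dir, "cohort_correlations.csv"))
  for (co in names(result$pcf)) {
    readr::write_csv(tidy(result$pcf[[co]]$envelope),
                     file.path(dir, paste0("pcf_", co, ".csv")))
    readr::write_csv(result$pcf[[co]]$intervals,
                     file.path(dir, paste0("pcf_intervals_", co, ".csv")))
  }
  for (co in names(result$pccf)) {
    readr::write_csv(tidy(result$pccf[[co]]$envelope),
                     file.path(dir, paste0("pccf_AL_", co, ".csv")))
    readr::write_csv(result$pccf[[co]]$intervals,
                     file.path(dir, paste0("pccf_intervals_AL_", co, ".csv")))
  }
  invisible(dir)
}
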