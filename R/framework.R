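#' Hypothesis labels of the recruitment decision framework
#'
#' The seven terminal hypotheses: distance seed limitation (`SL_DIS`),
#' density seed limitation (`SL_DEN`), small-scale allogenic habitat
#' patchiness (`HP_AL_SS`), static and dynamic large-scale allogenic habitat
#' patchiness (`HP_AL_LS_STAT`, `HP_AL_LS_DYN`), and autogenic facilitation
#' and competition (`HP_AU_FA`, `HP_AU_CO`).
#'
#' @return Character vector of hypothesis identifiers.
#' @export
hypothesis_labels <- function() {
  c("SL_DIS", "SL_DEN", "HP_AL_SS", "HP_AL_LS_STAT", "HP_AL_LS_DYN",
    "HP_AU_FA", "HP_AU_CO")
}

#' Bundle the statistical evidence for the decision framework
#'
#' Collects the outputs of the pipeline stages into the inputs the decision
#' tree consumes.
#'
#' @param iso_ui Logical: do isolated unbranched individuals occur?
#' @param pcf_verdicts Tibble with one row per cohort: `cohort`, `direction`
#'   (`"above"`, `"none"`, `"below"`: sign of the significant PCF envelope
#'   deviation, if any) and `cluster_scale` (m, `NA` when none). All five
#'   cohorts must be present.
#' @param pccf_intervals Tibble of significant cross-correlation intervals of
#'   each cohort versus large adults: columns `cohort`, `sign` (`"above"` /
#'   `"below"`), `r_start`, `r_end`. Zero rows when nothing is significant;
#'   must not contain `A_L` itself.
#' @param corr1 An [distance_sl_test()] result.
#' @param corr2 A [static_vs_dynamic()] result.
#' @return A list of class `evidence_bundle`.
#' @export
evidence_bundle <- function(iso_ui, pcf_verdicts, pccf_intervals, corr1, corr2) {
  missing <- character(0)
  if (!is.logical(iso_ui) || length(iso_ui) != 1 || is.na(iso_ui)) missing <- c(missing, "iso_ui")
  if (!is.data.frame(pcf_verdicts) ||
      !all(c("cohort", "direction", "cluster_scale") %in% names(pcf_verdicts)) ||
      !setequal(pcf_verdicts$cohort, cohort_levels())) {
    missing <- c(missing, "pcf_verdicts (all five cohorts)")
  }
  if (!is.data.frame(pccf_intervals) ||
      !all(c("cohort", "sign") %in% names(pccf_intervals)) ||
      "A_L" %in% pccf_intervals$cohort) {
    missing <- c(missing, "pccf_intervals (non-A_L cohorts only)")
  }
  if (!inherits(corr1, "sl_test")) missing <- c(missing, "corr1 (sl_test)")
  if (!inherits(corr2, "corr2_test")) missing <- c(missing, "corr2 (corr2_test)")
  if (length(missing)) {
    abort(paste0("incomplete or invalid evidence bundle: ",
                 paste(missing, collapse = "; ")))
  }
  structure(
    list(iso_ui = iso_ui, pcf_verdicts = tibble::as_tibble(pcf_verdicts),
         pccf_intervals = tibble::as_tibble(pccf_intervals),
         corr1 = corr1, corr2 = corr2),
    class = "evidence_bundle"
  )
}

#' Evaluate the recruitment hypothesis framework
#'
#' Maps an [evidence_bundle()] onto a supported/rejected verdict for each of
#' the seven recruitment hypotheses:
#' * `SL_DIS` is supported iff the adult-cover versus recruit-density
#'   correlation test (Corr1) is significant;
#' * `SL_DEN` and `HP_AL_SS` are supported iff isolated unbranched
#'   individuals occur; pattern analysis alone cannot separate the two (a
#'   seed-addition experiment would be needed), so both carry a shared
#'   caveat and always agree;
#' * large-scale allogenic HP is inferred when at least one cohort PCF lies
#'   significantly above its envelope with a cluster scale exceeding
#'   `large_scale` (default 10 m); given that, the static/dynamic split
#'   follows the between-cohort density-correlation verdict (Corr2);
#' * `HP_AU_FA` (`HP_AU_CO`) is supported iff any cohort's cross-correlation
#'   against large adults deviates significantly above (below) its envelope.
#'
#' The evaluation is a pure function of the bundle, and `HP_AL_LS_STAT` and
#' `HP_AL_LS_DYN` are never both supported.
#'
#' @param evidence An [evidence_bundle()].
#' @param large_scale Cluster-scale threshold (m) separating small- from
#'   large-scale clustering (default 10).
#' @return A tibble of class `hypothesis_report` with columns `hypothesis`,
#'   `supported` (`"y"`/`"n"`), `evidence`, `caveat`.
#' @export
evaluate_framework <- function(evidence, large_scale = 10) {
  if (!inherits(evidence, "evidence_bundle")) {
    abort("`evidence` must be an evidence_bundle()")
  }
  sep_caveat <- "not separable from its sibling hypothesis by pattern analysis alone"

  sl_dis <- evidence$corr1$verdict == "supported"
  sl_den <- evidence$iso_ui
  ls_cohorts <- evidence$pcf_verdicts |>
    dplyr::filter(.data$direction == "above",
                  !is.na(.data$cluster_scale), .data$cluster_scale > large_scale)
  hp_ls <- nrow(ls_cohorts) > 0
  hp_stat <- hp_ls && evidence$corr2$verdict == "static"
  hp_dyn <- hp_ls && evidence$corr2$verdict == "dynamic"
  hp_fa <- any(evidence$pccf_intervals$sign == "above")
  hp_co <- any(evidence$pccf_intervals$sign == "below")

  yn <- function(x) if (isTRUE(x)) "y" else "n"
  out <- tibble::tibble(
    hypothesis = hypothesis_labels(),
    supported = c(yn(sl_dis), yn(sl_den), yn(sl_den), yn(hp_stat), yn(hp_dyn),
                  yn(hp_fa), yn(hp_co)),
    evidence = c(
      sprintf("Corr1 %s", evidence$corr1$verdict),
      sprintf("isolated unbranched individuals %s", if (sl_den) "present" else "absent"),
      sprintf("isolated unbranched individuals %s", if (sl_den) "present" else "absent"),
      sprintf("large-scale clustering in %d cohort(s); Corr2 %s (%d/10 pairs significant)",
              nrow(ls_cohorts), evidence$corr2$verdict, evidence$corr2$n_significant),
      sprintf("large-scale clustering in %d cohort(s); Corr2 %s (%d/10 pairs significant)",
              nrow(ls_cohorts), evidence$corr2$verdict, evidence$corr2$n_significant),
      sprintf("%d significant positive PCCF interval(s) vs A_L",
              sum(evidence$pccf_intervals$sign == "above")),
      sprintf("%d significant negative PCCF interval(s) vs A_L",
              sum(evidence$pccf_intervals$sign == "below"))
    ),
    caveat = c(NA, sep_caveat, sep_caveat, NA, NA, NA, NA)
  )
  class(out) <- c("hypothesis_report", class(out))
  out
}

#' Format a hypothesis report as a markdown table
#'
#' Two-row table (hypotheses, y/n verdicts) in the conventional summary
#' layout.
#'
#' @param report A [evaluate_framework()] result.
#' @return A character scalar of markdown.
#' @export
report_markdown <- function(report) {
  paste0(
    "| Hypotheses: | ", paste(report$hypothesis, collapse = " | "), " |\n",
    "|---", strrep("|---", nrow(report)), "|\n",
    "| Supported: | ", paste(report$supported, collapse = " | "), " |\n"
  )
}
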