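# Stratified pooling over study-level covariates and leave-one-out
# sensitivity analysis.

.stratifiers <- c("ethnicity", "genotyping_method", "control_source",
                  "quality", "language")

# Map each study to its stratum label under a stratifier. Quality is the
# Newcastle-Ottawa dichotomy: higher = NOS >= 7, lower = NOS < 7.
stratum_labels <- function(studies, stratifier) {
  stratifier <- match.arg(stratifier, .stratifiers)
  labels <- if (stratifier == "quality") {
    ifelse(studies$nos_score >= 7, "higher", "lower")
  } else {
    studies[[stratifier]]
  }
  missing <- which(is.na(labels))
  if (length(missing) > 0L)
    stop(sprintf("study %s: missing value for stratifier '%s'",
                 studies$study_id[missing[1]], stratifier))
  labels
}

#' Subgroup (stratified) pooling
#'
#' Splits the studies by a study-level covariate and pools each stratum
#' separately with the chosen model mode. Strata in which no study
#' reports the comparison's counts are omitted with a message;
#' single-study strata return that study's estimate (flagged by
#' `n_studies = 1`).
#'
#' @param studies A `study_table`.
#' @param comparison Comparison name as in [study_effects()].
#' @param stratifier One of `"ethnicity"`, `"genotyping_method"`,
#'   `"control_source"`, `"quality"` (NOS >= 7 vs < 7), `"language"`.
#' @param model Model mode as in [pool()].
#' @return Named list of `pooled_result`, one per non-empty stratum.
#' @examples
#' subgroup_analysis(hmox1_studies(), "genotype", "control_source")
#' @export
subgroup_analysis <- function(studies, comparison, stratifier,
                              model = c("dl", "rule")) {
  model <- match.arg(model)
  labels <- stratum_labels(studies, stratifier)
  out <- list()
  for (stratum in unique(labels)) {
    sub <- studies[labels == stratum, , drop = FALSE]
    effects <- tryCatch(study_effects(sub, comparison), error = function(e) NULL)
    if (is.null(effects)) {
      message("stratum '", stratum, "' omitted: no study reports '",
              comparison, "' counts")
      next
    }
    out[[stratum]] <- pool(effects, model)
  }
  out
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the comparison n times, each time omitting one study, to
#' show how much any single study drives the pooled estimate.
#'
#' @param studies A `study_table` in which at least two studies report
#'   the comparison.
#' @param comparison Comparison name as in [study_effects()].
#' @param model Model mode as in [pool()]; re-applied per subset (so the
#'   rule-based mode may switch models across omissions).
#' @return A `sensitivity_report`: named list of `pooled_result` (name =
#'   omitted study), plus `or_range` (min/max pooled OR across
#'   omissions) and `stable` (TRUE when every omission keeps the pooled
#'   OR on the same side of 1 and all omission CIs pairwise overlap).
#' @examples
#' leave_one_out(hmox1_studies(), "genotype")
#' @export
leave_one_out <- function(studies, comparison, model = c("dl", "rule")) {
  model <- match.arg(model)
  effects <- study_effects(studies, comparison)
  if (nrow(effects) < 2L)
    stop("leave-one-out needs at least 2 studies reporting '", comparison, "'")
  ids <- effects$study_id
  results <- lapply(ids, function(id) {
    pool(effects[effects$study_id != id, , drop = FALSE], model)
  })
  names(results) <- ids
  ors <- vapply(results, `[[`, numeric(1), "pooled_or")
  lows <- vapply(results, `[[`, numeric(1), "ci_low")
  highs <- vapply(results, `[[`, numeric(1), "ci_high")
  same_side <- all(ors > 1) || all(ors < 1) || all(ors == 1)
  overlap <- max(lows) <= min(highs)
  structure(list(results = results,
                 or_range = c(min = min(ors), max = max(ors)),
                 stable = same_side && overlap),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Leave-one-out sensitivity analysis (%d omissions)\n",
              length(x$results)))
  for (id in names(x$results)) {
    r <- x$results[[id]]
    cat(sprintf("  without %-12s OR %.2f [%.2f, %.2f]\n",
                paste0(id, ":"), r$pooled_or, r$ci_low, r$ci_high))
  }
  cat(sprintf("  pooled OR range [%.2f, %.2f]; %s\n",
              x$or_range["min"], x$or_range["max"],
              if (x$stable) "stable" else "NOT stable"))
  invisible(x)
}
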