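# End-to-end orchestration: one comparison -> overall pooling, optional
# subgroups, sensitivity, bias diagnostics and funnel data, with a
# provenance block, serialized to JSON + TSV.

#' Run a full meta-analysis for one comparison
#'
#' @param studies A `study_table`.
#' @param comparison Comparison name as in [study_effects()].
#' @param model Model mode as in [pool()]; the default pools every
#'   comparison with DerSimonian-Laird random effects.
#' @param subgroups Character vector of stratifiers (see
#'   [subgroup_analysis()]) to analyse; empty for none.
#' @param sensitivity Run leave-one-out sensitivity analysis?
#' @param bias Run Egger and Begg tests? (Requires enough studies; run
#'   with a notice otherwise.)
#' @param seed Optional seed recorded in provenance (for synthetic
#'   inputs).
#' @return A `meta_report`: `comparison`, `model_mode`, `effects`,
#'   `overall` (`pooled_result`), `forest` (forest-plot data frame),
#'   optional `subgroups`, `sensitivity`, `bias` (`egger`/`begg`),
#'   `funnel`, and `provenance`.
#' @examples
#' rep <- run_analysis(hmox1_studies(), "genotype", subgroups = "ethnicity")
#' rep$overall
#' @export
run_analysis <- function(studies, comparison, model = c("dl", "rule"),
                         subgroups = character(0), sensitivity = FALSE,
                         bias = TRUE, seed = NULL) {
  model <- match.arg(model)
  effects <- study_effects(studies, comparison)
  overall <- pool(effects, model)
  report <- list(comparison = comparison, model_mode = model,
                 effects = effects, overall = overall,
                 forest = forest_data(effects, overall))
  if (length(subgroups) > 0L) {
    report$subgroups <- lapply(
      stats::setNames(subgroups, subgroups),
      function(s) subgroup_analysis(studies, comparison, s, model))
  }
  if (sensitivity) {
    report$sensitivity <- leave_one_out(studies, comparison, model)
  }
  if (bias) {
    report$bias <- list(
      egger = tryCatch(egger_test(effects), error = function(e) {
        message("Egger test skipped: ", conditionMessage(e)); NULL
      }),
      begg = tryCatch(begg_test(effects), error = function(e) {
        message("Begg test skipped: ", conditionMessage(e)); NULL
      }))
    report$funnel <- funnel_data(effects, overall)
  }
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("hmoxmeta")),
    n_input_studies = nrow(studies),
    input_digest = study_digest(studies),
    model_mode = model,
    seed = seed)
  class(report) <- "meta_report"
  report
}

# Order-insensitive content digest of the study table (no external
# hashing dependency: a fixed-precision serialization is enough to
# detect input changes in provenance).
study_digest <- function(studies) {
  df <- as.data.frame(studies)[order(studies$study_id), .study_cols]
  txt <- paste(capture_csv(df), collapse = "\n")
  sprintf("sum%08x-len%d", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 0xFFFFFFFF,
          nchar(txt))
}

capture_csv <- function(df) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  close(con)
  out
}

#' @export
print.meta_report <- function(x, ...) {
  cat("Meta-analysis report: comparison '", x$comparison, "' (model mode: ",
      x$model_mode, ")\n\n", sep = "")
  print(x$overall)
  if (!is.null(x$subgroups)) {
    for (s in names(x$subgroups)) {
      cat("\nSubgroups by ", s, ":\n", sep = "")
      for (stratum in names(x$subgroups[[s]])) {
        r <- x$subgroups[[s]][[stratum]]
        cat(sprintf("  %-20s (k=%d) OR %.2f [%.2f, %.2f]\n", stratum,
                    r$n_studies, r$pooled_or, r$ci_low, r$ci_high))
      }
    }
  }
  if (!is.null(x$sensitivity)) { cat("\n"); print(x$sensitivity) }
  if (!is.null(x$bias)) {
    cat("\n")
    if (!is.null(x$bias$egger)) print(x$bias$egger)
    if (!is.null(x$bias$begg)) print(x$bias$begg)
  }
  invisible(x)
}

pooled_as_list <- function(p) {
  out <- unclass(p)
  out$weights <- as.list(out$weights)
  out
}

#' Serialize a meta-analysis report
#'
#' Writes `<stem>.json` (all pooled fields at full precision plus a
#' 2-decimal "printed" view of the headline numbers), `<stem>_forest.tsv`
#' (study_id, OR, CI, weight %) and, when bias diagnostics were run,
#' `<stem>_funnel.tsv` (study_id, log_or, se). Field order and float
#' formatting are deterministic, so reports are byte-identical across
#' runs on the same input and seed.
#'
#' @param report A `meta_report`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; defaults to the comparison name.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir, stem = report$comparison) {
  stopifnot(inherits(report, "meta_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)

  body <- list(
    comparison = report$comparison,
    model_mode = report$model_mode,
    overall = pooled_as_list(report$overall),
    printed = list(
      or = round(report$overall$pooled_or, 2),
      ci_low = round(report$overall$ci_low, 2),
      ci_high = round(report$overall$ci_high, 2),
      i_squared = round(report$overall$i_squared),
      p_Q = round(report$overall$p_Q, 2)),
    provenance = report$provenance)
  if (!is.null(report$subgroups))
    body$subgroups <- lapply(report$subgroups, function(s) lapply(s, pooled_as_list))
  if (!is.null(report$sensitivity))
    body$sensitivity <- list(
      results = lapply(report$sensitivity$results, pooled_as_list),
      or_range = as.list(report$sensitivity$or_range),
      stable = report$sensitivity$stable)
  if (!is.null(report$bias))
    body$bias <- list(egger = if (!is.null(report$bias$egger)) unclass(report$bias$egger),
                      begg = if (!is.null(report$bias$begg)) unclass(report$bias$begg))

  json_path <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(body, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- c(files, json_path)

  forest_path <- file.path(dir, paste0(stem, "_forest.tsv"))
  utils::write.table(report$forest, forest_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- c(files, forest_path)

  if (!is.null(report$funnel)) {
    funnel_path <- file.path(dir, paste0(stem, "_funnel.tsv"))
    utils::write.table(report$funnel$points[c("study_id", "log_or", "se")],
                       funnel_path, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, funnel_path)
  }
  invisible(files)
}
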