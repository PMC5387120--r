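# Per-study effect sizes: Woolf log odds ratio with its large-sample
# variance 1/a + 1/b + 1/c + 1/d.

Z975 <- 1.959964

#' Woolf log odds ratio for a 2x2 table
#'
#' @param t A `fourfold` table.
#' @param correction Continuity correction added to all four cells when
#'   any cell is zero (default 0.5). The `corrected` flag records whether
#'   it was applied.
#' @param study_id Optional label carried into the result.
#' @return A one-row data frame (an effect estimate): `study_id`,
#'   `log_or`, `var`, `se`, `or`, `ci_low`, `ci_high` (95% bounds on the
#'   OR scale), `corrected`.
#' @examples
#' woolf_effect(fourfold(26, 38, 12, 44))
#' @export
woolf_effect <- function(t, correction = 0.5, study_id = NA_character_) {
  stopifnot(inherits(t, "fourfold"))
  if (t$degenerate) stop("degenerate 2x2 table (all cells zero): no effect estimate")
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + correction
  log_or <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  v <- sum(1 / cells)
  effect_row(study_id, log_or, v, corrected)
}

effect_row <- function(study_id, log_or, var, corrected = FALSE) {
  se <- sqrt(var)
  data.frame(study_id = study_id, log_or = log_or, var = var, se = se,
             or = exp(log_or),
             ci_low = exp(log_or - Z975 * se),
             ci_high = exp(log_or + Z975 * se),
             corrected = corrected, stringsAsFactors = FALSE)
}

#' Per-study effects for a named comparison
#'
#' Builds the comparison's 2x2 table for every study that reports the
#' required block and computes the Woolf effect for each. Studies lacking
#' the block are excluded (this is how the five allele studies and seven
#' genotype studies coexist in one table).
#'
#' @param studies A `study_table`.
#' @param comparison One of `"allele_S"`, `"allele_M"`, `"allele_L"`
#'   (that allele vs the other two), `"genotype"` (type I vs type II),
#'   `"severity"` (type I vs type II, more- vs less-severe strata).
#' @param correction Continuity correction passed to [woolf_effect()].
#' @return A data frame of effect estimates, one row per contributing
#'   study.
#' @examples
#' study_effects(hmox1_studies(), "genotype")
#' @export
study_effects <- function(studies,
                          comparison = c("allele_S", "allele_M", "allele_L",
                                         "genotype", "severity"),
                          correction = 0.5) {
  comparison <- match.arg(comparison)
  rows <- lapply(seq_len(nrow(studies)), function(i) {
    tab <- comparison_table(studies[i, ], comparison)
    if (is.null(tab)) return(NULL)
    woolf_effect(tab, correction, study_id = studies$study_id[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no study reports the counts needed for comparison '", comparison, "'")
  rownames(out) <- NULL
  out
}
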