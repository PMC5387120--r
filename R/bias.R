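# Publication-bias diagnostics: Egger regression and the Begg-Mazumdar
# rank-correlation test, plus funnel-plot data.

#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `y_i = theta_i/se_i`
#' on precision `x_i = 1/se_i`. A non-zero intercept indicates
#' small-study asymmetry; the test is a two-sided t on the intercept with
#' n - 2 residual degrees of freedom.
#'
#' @param effects Data frame of effect estimates (at least 3 rows, with
#'   varying precision).
#' @return An `egger_test`: `intercept`, `se`, `t`, `df`, `p`, `slope`.
#' @examples
#' egger_test(study_effects(hmox1_studies(), "allele_L"))
#' @export
egger_test <- function(effects) {
  check_effects(effects)
  n <- nrow(effects)
  if (n < 3L) stop("Egger regression needs at least 3 studies, got ", n)
  x <- 1 / effects$se
  y <- effects$log_or / effects$se
  if (stats::var(x) == 0)
    stop("Egger regression degenerate: all studies have equal precision")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  intercept <- sm["(Intercept)", "Estimate"]
  se_b0 <- sm["(Intercept)", "Std. Error"]
  tval <- intercept / se_b0
  df <- n - 2L
  structure(list(intercept = intercept, se = se_b0, t = tval, df = df,
                 p = 2 * stats::pt(-abs(tval), df),
                 slope = sm["x", "Estimate"], n = n),
            class = "egger_test")
}

#' @export
print.egger_test <- function(x, ...) {
  cat(sprintf("Egger regression test (n = %d)\n", x$n))
  cat(sprintf("  intercept = %.4f (SE %.4f), t = %.3f, df = %d, p = %s\n",
              x$intercept, x$se, x$t, x$df, format_p(x$p)))
  invisible(x)
}

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Kendall rank correlation between the variance-standardized deviates
#' `t_i = (theta_i - theta_bar) / sqrt(var_i - 1/sum(w))` (theta_bar the
#' fixed-effect pooled estimate) and the sampling variances. The test
#' statistic is Kendall's score S = #concordant - #discordant pairs,
#' referred to the normal approximation
#' `z = S / sqrt(n(n-1)(2n+5)/18)` with no continuity correction.
#'
#' @param effects Data frame of effect estimates (at least 2 rows).
#' @return A `begg_test`: `S`, `var_S`, `z`, `p` (two-sided normal),
#'   `tau` (Kendall correlation), `ties` flag.
#' @details Ties in either ranking contribute zero to S; the null
#'   variance is left unadjusted and a warning is emitted, since the
#'   normal approximation is then conservative. A deviate whose
#'   conditional variance `var_i - 1/sum(w)` is non-positive is guarded
#'   to a small positive value, with a warning.
#' @export
begg_test <- function(effects) {
  check_effects(effects)
  n <- nrow(effects)
  if (n < 2L) stop("Begg test needs at least 2 studies, got ", n)
  w <- 1 / effects$var
  pooled <- sum(w * effects$log_or) / sum(w)
  cond_var <- effects$var - 1 / sum(w)
  if (any(cond_var <= 0)) {
    warning("non-positive conditional variance for some studies; guarded to a small positive value")
    cond_var <- pmax(cond_var, .Machine$double.eps)
  }
  t_i <- (effects$log_or - pooled) / sqrt(cond_var)
  # Kendall score over all n(n-1)/2 pairs; ties contribute 0.
  S <- 0L
  ties <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      prod_sign <- sign(t_i[j] - t_i[i]) * sign(effects$var[j] - effects$var[i])
      if (prod_sign == 0) ties <- TRUE
      S <- S + prod_sign
    }
  }
  if (ties) warning("ties present in Begg ranks; variance left unadjusted")
  var_S <- n * (n - 1) * (2 * n + 5) / 18
  z <- S / sqrt(var_S)
  structure(list(S = S, var_S = var_S, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 tau = S / (n * (n - 1) / 2), n = n, ties = ties),
            class = "begg_test")
}

#' @export
print.begg_test <- function(x, ...) {
  cat(sprintf("Begg-Mazumdar rank correlation test (n = %d)\n", x$n))
  cat(sprintf("  Kendall S = %d (tau = %.3f), z = %.3f, p = %s\n",
              x$S, x$tau, x$z, format_p(x$p)))
  invisible(x)
}

#' Funnel-plot data
#'
#' @param effects Data frame of effect estimates.
#' @param pooled Optional `pooled_result` supplying the reference line.
#' @return List with `points` (study_id, or, log_or, se) and
#'   `reference_or` (pooled OR, or `NA` when no pooled result is given).
#'   Plot-ready; no rendering.
#' @export
funnel_data <- function(effects, pooled = NULL) {
  points <- if (is.null(effects) || nrow(effects) == 0L) {
    data.frame(study_id = character(), or = numeric(), log_or = numeric(),
               se = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(study_id = effects$study_id, or = effects$or,
               log_or = effects$log_or, se = effects$se,
               stringsAsFactors = FALSE)
  }
  list(points = points,
       reference_or = if (is.null(pooled)) NA_real_ else pooled$pooled_or)
}
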