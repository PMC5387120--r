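# Fixed-effect (inverse variance) and DerSimonian-Laird random-effects
# pooling of log odds ratios, with Cochran Q and I-squared.

check_effects <- function(effects) {
  stopifnot(is.data.frame(effects),
            all(c("log_or", "var") %in% names(effects)))
  if (nrow(effects) == 0L) stop("cannot pool an empty set of effects")
  if (any(effects$var <= 0)) stop("effect variances must be positive")
  effects
}

#' Cochran Q and I-squared heterogeneity statistics
#'
#' Q is computed with the fixed-effect inverse-variance weights;
#' `i_squared = max(0, (Q - df)/Q) * 100`. The conventional bands are
#' low (< 25%), moderate (25--75%) and high (> 75%) inconsistency.
#'
#' @param effects Data frame of effect estimates ([study_effects()]).
#' @return List with `Q`, `df`, `p_Q` (chi-square upper tail),
#'   `i_squared` (percent) and `band` (`"low"`, `"moderate"`, `"high"`,
#'   or `NA` for fewer than two studies, when the test is degenerate).
#' @export
heterogeneity <- function(effects) {
  check_effects(effects)
  k <- nrow(effects)
  if (k < 2L)
    return(list(Q = 0, df = 0L, p_Q = 1, i_squared = 0, band = NA_character_))
  w <- 1 / effects$var
  pooled <- sum(w * effects$log_or) / sum(w)
  Q <- sum(w * (effects$log_or - pooled)^2)
  df <- k - 1L
  i2 <- max(0, (Q - df) / Q) * 100
  band <- if (i2 < 25) "low" else if (i2 <= 75) "moderate" else "high"
  list(Q = Q, df = df, p_Q = stats::pchisq(Q, df, lower.tail = FALSE),
       i_squared = i2, band = band)
}

#' Fixed-effect inverse-variance pooling
#'
#' Weights `w_i = 1/var_i`; pooled log OR is the weighted mean, pooled
#' SE is `1/sqrt(sum(w))`. Between-study variance is zero by definition
#' of the model.
#'
#' @param effects Data frame of effect estimates.
#' @return A `pooled_result`.
#' @export
pool_fixed_iv <- function(effects) {
  check_effects(effects)
  w <- 1 / effects$var
  pool_from_weights(effects, w, model = "fixed_iv", tau_squared = 0)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau^2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`
#' from the fixed-effect pass; random-effects weights are
#' `1/(var_i + tau^2)`. Q and I-squared are always reported from the
#' fixed-weight pass. With one study, or whenever `Q <= df`, tau^2
#' truncates to zero and the result equals [pool_fixed_iv()].
#'
#' @param effects Data frame of effect estimates.
#' @return A `pooled_result`.
#' @examples
#' pool_random_dl(study_effects(hmox1_studies(), "genotype"))
#' @export
pool_random_dl <- function(effects) {
  check_effects(effects)
  het <- heterogeneity(effects)
  w <- 1 / effects$var
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (nrow(effects) < 2L || C <= 0) 0 else max(0, (het$Q - het$df) / C)
  w_star <- 1 / (effects$var + tau2)
  pool_from_weights(effects, w_star, model = "random_dl", tau_squared = tau2)
}

pool_from_weights <- function(effects, w, model, tau_squared) {
  het <- heterogeneity(effects)
  pooled <- sum(w * effects$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- pooled / se
  structure(list(
    model = model, n_studies = nrow(effects),
    pooled_log_or = pooled, pooled_se = se,
    pooled_or = exp(pooled),
    ci_low = exp(pooled - Z975 * se), ci_high = exp(pooled + Z975 * se),
    z = z, p_value = 2 * stats::pnorm(-abs(z)),
    Q = het$Q, df = het$df, p_Q = het$p_Q,
    i_squared = het$i_squared, i_squared_band = het$band,
    tau_squared = tau_squared,
    weights = stats::setNames(w / sum(w), effects$study_id),
    study_ids = effects$study_id), class = "pooled_result")
}

#' Choose the pooling model from the heterogeneity p-value
#'
#' The classical rule: fixed effect when the Q test shows no
#' heterogeneity (`p_Q` above the threshold), random effects otherwise;
#' the boundary itself selects random effects. The package's default
#' pipeline uses DerSimonian-Laird throughout, with this rule available
#' as an explicit mode.
#'
#' @param p_Q Heterogeneity p-value in `[0, 1]`.
#' @param threshold Decision threshold (default 0.10).
#' @return `"fixed_iv"` or `"random_dl"`.
#' @export
select_model <- function(p_Q, threshold = 0.10) {
  stopifnot(p_Q >= 0, p_Q <= 1)
  if (p_Q > threshold) "fixed_iv" else "random_dl"
}

#' Pool a set of effects under a model mode
#'
#' @param effects Data frame of effect estimates.
#' @param model `"dl"` (DerSimonian-Laird throughout, the default) or
#'   `"rule"` (fixed effect when `p_Q` > 0.10, random effects otherwise).
#' @return A `pooled_result`.
#' @export
pool <- function(effects, model = c("dl", "rule")) {
  model <- match.arg(model)
  if (model == "dl") return(pool_random_dl(effects))
  het <- heterogeneity(effects)
  if (select_model(het$p_Q) == "fixed_iv") pool_fixed_iv(effects)
  else pool_random_dl(effects)
}

#' @export
print.pooled_result <- function(x, digits = 2, ...) {
  model_name <- c(fixed_iv = "fixed-effect (inverse variance)",
                  random_dl = "random-effects (DerSimonian-Laird)")[x$model]
  cat(sprintf("%s meta-analysis of %d studies\n", model_name, x$n_studies))
  cat(sprintf("  OR %.*f [%.*f, %.*f], z = %.2f, p = %s\n",
              digits, x$pooled_or, digits, x$ci_low, digits, x$ci_high,
              x$z, format_p(x$p_value)))
  cat(sprintf("  Heterogeneity: Q = %.2f (df = %d, p = %s), I^2 = %.0f%%%s, tau^2 = %.4f\n",
              x$Q, x$df, format_p(x$p_Q), x$i_squared,
              if (is.na(x$i_squared_band)) "" else sprintf(" (%s)", x$i_squared_band),
              x$tau_squared))
  invisible(x)
}

#' Forest-plot data for a pooled comparison
#'
#' @param effects Data frame of effect estimates.
#' @param pooled The corresponding `pooled_result`.
#' @return Data frame (study_id, or, ci_low, ci_high, weight_pct) with a
#'   final `"POOLED"` row; plot-ready, no rendering.
#' @export
forest_data <- function(effects, pooled) {
  stopifnot(inherits(pooled, "pooled_result"))
  rbind(
    data.frame(study_id = effects$study_id, or = effects$or,
               ci_low = effects$ci_low, ci_high = effects$ci_high,
               weight_pct = 100 * unname(pooled$weights[effects$study_id]),
               stringsAsFactors = FALSE),
    data.frame(study_id = "POOLED", or = pooled$pooled_or,
               ci_low = pooled$ci_low, ci_high = pooled$ci_high,
               weight_pct = 100, stringsAsFactors = FALSE))
}
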