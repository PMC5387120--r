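# Case-control study simulator. Controls are drawn under tri-allelic
# Hardy-Weinberg equilibrium; case status is linked to L-carrier
# (type I) genotype through a study-level log odds ratio with normal
# between-study heterogeneity. This is a carrier-level (dominant) effect
# model, matching the type I vs type II contrast: allele-level odds
# ratios then emerge from the genotype model rather than being imposed.

#' Simulation configuration
#'
#' @param n_studies Number of studies to generate.
#' @param n_cases,n_controls Per-study group sizes: a single number
#'   (fixed) or a length-2 range sampled uniformly per study.
#' @param p_alleles Named control allele frequencies `c(S=, M=, L=)`
#'   summing to 1; `L` must be positive (the carrier model needs
#'   carriers). Defaults approximate a (GT)n class distribution with a
#'   common S/M bulk and a ~10% L tail.
#' @param mu True carrier (type I vs type II) log odds ratio.
#' @param tau_squared Between-study variance of the study-level log OR.
#' @param severity_log_or If non-`NULL`, severity blocks are generated:
#'   cases split into less/more-severe strata with this carrier log OR
#'   on severity (0 = null association).
#' @param selection Optional selective-publication rule
#'   `list(prob =, alpha =)`: after generation, a study whose two-sided
#'   genotype-association p-value exceeds `alpha` is suppressed with
#'   probability `prob`.
#' @param seed Root random seed (required; per-study substreams are
#'   derived from it).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_studies = 7,
                       n_cases = c(50, 250), n_controls = c(30, 270),
                       p_alleles = c(S = 0.45, M = 0.45, L = 0.10),
                       mu = log(1.8), tau_squared = 0.05,
                       severity_log_or = NULL,
                       selection = NULL,
                       seed) {
  if (missing(seed)) stop("a root seed is required for reproducibility")
  stopifnot(n_studies >= 1, all(n_cases >= 1), all(n_controls >= 1),
            length(n_cases) %in% 1:2, length(n_controls) %in% 1:2,
            tau_squared >= 0)
  p <- p_alleles[c("S", "M", "L")]
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p_alleles must be named S, M, L, non-negative and sum to 1")
  if (p[["L"]] <= 0)
    stop("p_L must be positive: the carrier effect model is degenerate without L alleles")
  if (!is.null(selection))
    stopifnot(is.list(selection), all(c("prob", "alpha") %in% names(selection)),
              selection$prob >= 0, selection$prob <= 1,
              selection$alpha >= 0, selection$alpha <= 1)
  structure(list(n_studies = as.integer(n_studies), n_cases = n_cases,
                 n_controls = n_controls, p_alleles = p, mu = mu,
                 tau_squared = tau_squared, severity_log_or = severity_log_or,
                 selection = selection, seed = as.integer(seed)),
            class = "sim_config")
}

draw_size <- function(range) {
  if (length(range) == 1L) as.integer(range)
  else sample(seq.int(range[1], range[2]), 1L)
}

# HWE genotype probabilities for the six unordered S/M/L genotypes.
hwe_genotype_probs <- function(p) {
  c(SS = p[["S"]]^2, SM = 2 * p[["S"]] * p[["M"]], SL = 2 * p[["S"]] * p[["L"]],
    MM = p[["M"]]^2, ML = 2 * p[["M"]] * p[["L"]], LL = p[["L"]]^2)
}

allele_counts_from_genotypes <- function(g) {
  c(S = 2 * g[["SS"]] + g[["SM"]] + g[["SL"]],
    M = 2 * g[["MM"]] + g[["SM"]] + g[["ML"]],
    L = 2 * g[["LL"]] + g[["SL"]] + g[["ML"]])
}

#' Simulate one case-control study
#'
#' Control genotypes are multinomial under tri-allelic HWE. The
#' study-level carrier log OR is `theta ~ Normal(mu, tau^2)`; case
#' carrier counts are binomial with probability derived from the control
#' carrier odds times `exp(theta)`. Case carrier genotypes (LL vs
#' L-heterozygote, and the heterozygote's partner allele) are split
#' using the control HWE conditional distribution -- a modeling choice
#' that keeps allele counts consistent with genotype counts by
#' construction.
#'
#' @param config A `sim_config`.
#' @param seed Seed for this study's substream.
#' @param study_id Label for the generated record.
#' @return List with `study` (a one-row `study_table`-schema data
#'   frame), `theta` (the study's true carrier log OR), and
#'   `genotypes` (named 6-genotype count vectors for cases and
#'   controls, usable with [hwe_multiallelic()]).
#' @export
simulate_study <- function(config, seed, study_id = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  p <- config$p_alleles
  n_ca <- draw_size(config$n_cases)
  n_co <- draw_size(config$n_controls)

  gprob <- hwe_genotype_probs(p)
  ctrl_geno <- stats::setNames(
    as.vector(stats::rmultinom(1L, n_co, gprob)), names(gprob))
  ctrl_allele <- allele_counts_from_genotypes(ctrl_geno)
  ctrl_typeI <- ctrl_geno[["SL"]] + ctrl_geno[["ML"]] + ctrl_geno[["LL"]]

  theta <- stats::rnorm(1L, config$mu, sqrt(config$tau_squared))
  q0 <- 1 - (1 - p[["L"]])^2          # population carrier probability
  odds1 <- q0 / (1 - q0) * exp(theta)
  q1 <- odds1 / (1 + odds1)
  case_typeI <- stats::rbinom(1L, n_ca, q1)
  case_typeII <- n_ca - case_typeI

  # Case genotypes: carriers split LL vs heterozygote by the control HWE
  # conditional; heterozygote partner allele S vs M by relative frequency;
  # non-carriers multinomial over SS/SM/MM.
  p_LL_given_carrier <- p[["L"]]^2 / q0
  case_LL <- stats::rbinom(1L, case_typeI, p_LL_given_carrier)
  case_het <- case_typeI - case_LL
  case_SL <- stats::rbinom(1L, case_het, p[["S"]] / (p[["S"]] + p[["M"]]))
  case_ML <- case_het - case_SL
  noncar_probs <- c(SS = p[["S"]]^2, SM = 2 * p[["S"]] * p[["M"]], MM = p[["M"]]^2)
  noncar <- stats::setNames(
    as.vector(stats::rmultinom(1L, case_typeII, noncar_probs)), names(noncar_probs))
  case_geno <- c(SS = noncar[["SS"]], SM = noncar[["SM"]], SL = case_SL,
                 MM = noncar[["MM"]], ML = case_ML, LL = case_LL)
  case_allele <- allele_counts_from_genotypes(case_geno)

  sev <- rep(NA_integer_, 4L)
  if (!is.null(config$severity_log_or)) {
    p_more_carrier <- stats::plogis(config$severity_log_or)  # base rate 1/2
    more_typeI <- stats::rbinom(1L, case_typeI, p_more_carrier)
    more_typeII <- stats::rbinom(1L, case_typeII, 0.5)
    sev <- c(case_typeI - more_typeI, case_typeII - more_typeII,
             more_typeI, more_typeII)
  }

  study <- data.frame(
    study_id = study_id,
    year = sample(2000:2015, 1L),
    ethnicity = sample(.ethnicity_levels, 1L),
    genotyping_method = sample(.method_levels, 1L),
    control_source = sample(.source_levels, 1L),
    nos_score = sample(5:8, 1L),
    language = sample(.language_levels, 1L),
    case_S = case_allele[["S"]], case_M = case_allele[["M"]],
    case_L = case_allele[["L"]],
    ctrl_S = ctrl_allele[["S"]], ctrl_M = ctrl_allele[["M"]],
    ctrl_L = ctrl_allele[["L"]],
    case_typeI = case_typeI, case_typeII = case_typeII,
    ctrl_typeI = ctrl_typeI,
    ctrl_typeII = n_co - ctrl_typeI,
    less_typeI = sev[1], less_typeII = sev[2],
    more_typeI = sev[3], more_typeII = sev[4],
    stringsAsFactors = FALSE)
  list(study = study, theta = theta,
       genotypes = list(case = case_geno, control = ctrl_geno))
}

#' Simulate a full meta-analysis data set
#'
#' Draws `n_studies` studies from independent substreams of the root
#' seed, optionally applies the selective-publication rule, and returns
#' the data alongside the ground truth needed for recovery tests.
#'
#' @param config A `sim_config`.
#' @return List with `studies` (a validated `study_table`), `truth`
#'   (`mu`, `tau_squared`, per-study `theta`, ids of `suppressed`
#'   studies) and `genotypes` (per-study 6-genotype count lists).
#' @examples
#' sim <- simulate_meta(sim_config(n_studies = 5, seed = 42))
#' pool_random_dl(study_effects(sim$studies, "genotype"))
#' @export
simulate_meta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  study_seeds <- sample.int(.Machine$integer.max - 1L, config$n_studies + 1L)
  sims <- lapply(seq_len(config$n_studies), function(i) {
    simulate_study(config, seed = study_seeds[i],
                   study_id = sprintf("sim%02d", i))
  })
  studies <- do.call(rbind, lapply(sims, `[[`, "study"))
  theta <- vapply(sims, `[[`, numeric(1), "theta")
  names(theta) <- studies$study_id

  suppressed <- character(0)
  if (!is.null(config$selection)) {
    set.seed(study_seeds[config$n_studies + 1L])
    keep <- rep(TRUE, nrow(studies))
    for (i in seq_len(nrow(studies))) {
      eff <- woolf_effect(genotype_table(studies[i, ]))
      p_i <- 2 * stats::pnorm(-abs(eff$log_or / eff$se))
      if (p_i > config$selection$alpha &&
          stats::runif(1L) < config$selection$prob)
        keep[i] <- FALSE
    }
    suppressed <- studies$study_id[!keep]
    if (!any(keep))
      stop("selective-publication rule suppressed every simulated study")
    studies <- studies[keep, , drop = FALSE]
    rownames(studies) <- NULL
  }
  validate_studies(studies)
  class(studies) <- c("study_table", "data.frame")
  list(studies = studies,
       truth = list(mu = config$mu, tau_squared = config$tau_squared,
                    theta = theta, suppressed = suppressed),
       genotypes = lapply(sims, `[[`, "genotypes"))
}
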