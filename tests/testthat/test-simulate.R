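test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_studies = 4, seed = 101)
  a <- simulate_meta(cfg)
  b <- simulate_meta(cfg)
  expect_identical(a$studies, b$studies)
  expect_identical(a$truth, b$truth)
  one <- simulate_study(cfg, seed = 99)
  two <- simulate_study(cfg, seed = 99)
  expect_identical(one$study, two$study)
})

test_that("a seed is mandatory and degenerate frequencies are rejected", {
  expect_error(sim_config(n_studies = 3), "seed")
  expect_error(sim_config(p_alleles = c(S = 0.5, M = 0.5, L = 0), seed = 1),
               "p_L")
  expect_error(sim_config(p_alleles = c(S = 0.5, M = 0.3, L = 0.3), seed = 1),
               "sum to 1")
})

test_that("generated blocks satisfy the count-block invariants", {
  cfg <- sim_config(n_studies = 10, severity_log_or = 0, seed = 202)
  sim <- simulate_meta(cfg)
  s <- sim$studies
  expect_equal(nrow(s), 10)
  # allele totals are twice the subject totals, consistently per group
  case_n <- s$case_typeI + s$case_typeII
  ctrl_n <- s$ctrl_typeI + s$ctrl_typeII
  expect_equal(s$case_S + s$case_M + s$case_L, 2 * case_n)
  expect_equal(s$ctrl_S + s$ctrl_M + s$ctrl_L, 2 * ctrl_n)
  # L-carrier marginals are mutually consistent with L-allele counts
  for (i in seq_len(nrow(s))) {
    expect_silent(collapse_to_biallelic(s$case_L[i], s$case_typeI[i],
                                        s$case_typeII[i]))
    expect_silent(collapse_to_biallelic(s$ctrl_L[i], s$ctrl_typeI[i],
                                        s$ctrl_typeII[i]))
  }
  # severity strata partition the cases
  expect_equal(s$less_typeI + s$more_typeI, s$case_typeI)
  expect_equal(s$less_typeII + s$more_typeII, s$case_typeII)
  # and the whole table passes the reader's validation
  expect_silent(validate_studies(s))
})

test_that("expected carrier counts follow the dominant-model probability", {
  # q0 = 1 - (1 - p_L)^2 = 0.19 at p_L = 0.1
  cfg <- sim_config(n_studies = 30, n_cases = 200, n_controls = 1000,
                    p_alleles = c(S = 0.45, M = 0.45, L = 0.10),
                    mu = 0, tau_squared = 0, seed = 303)
  sim <- simulate_meta(cfg)
  mean_carriers <- mean(sim$studies$ctrl_typeI)
  expect_equal(mean_carriers, 190, tolerance = 0.05)  # 5% Monte-Carlo slack
})

test_that("the null model pools to an odds ratio near 1", {
  cfg <- sim_config(n_studies = 20, n_cases = 500, n_controls = 500,
                    mu = 0, tau_squared = 0, seed = 404)
  sim <- simulate_meta(cfg)
  pooled <- pool_random_dl(study_effects(sim$studies, "genotype"))
  expect_gt(pooled$ci_high, 1)
  expect_lt(pooled$ci_low, 1)
  expect_equal(pooled$pooled_or, 1, tolerance = 0.15)
})

test_that("simulated controls pass the multi-allelic HWE test at nominal rate", {
  cfg <- sim_config(n_studies = 1, n_cases = 50, n_controls = 500, seed = 1)
  set.seed(505)
  seeds <- sample.int(1e7, 400)
  rejections <- vapply(seeds, function(s) {
    g <- simulate_study(cfg, seed = s)$genotypes$control
    hwe_multiallelic(g, alleles = c("S", "M", "L"))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("selective publication suppresses only null-looking studies", {
  cfg <- sim_config(n_studies = 12, n_cases = c(30, 80), n_controls = c(30, 80),
                    mu = 0, tau_squared = 0,
                    selection = list(prob = 1, alpha = 0.99), seed = 606)
  # alpha = 0.99, prob = 1: nearly every study has p > 0.99? no -- suppression
  # applies to p > alpha, so almost none are suppressed
  sim <- simulate_meta(cfg)
  expect_gte(nrow(sim$studies), 10)
  # prob = 1 with alpha = 1 never suppresses
  cfg_none <- sim_config(n_studies = 6, selection = list(prob = 1, alpha = 1),
                         seed = 607)
  sim_none <- simulate_meta(cfg_none)
  expect_equal(nrow(sim_none$studies), 6)
  expect_equal(sim_none$truth$suppressed, character(0))
})

test_that("a fixture-like configuration runs the whole pipeline end to end", {
  cfg <- sim_config(n_studies = 7, n_cases = c(48, 256), n_controls = c(30, 266),
                    p_alleles = c(S = 0.45, M = 0.44, L = 0.11),
                    mu = log(1.8), tau_squared = 0.08, seed = 707)
  sim <- simulate_meta(cfg)
  report <- run_analysis(sim$studies, "genotype",
                         subgroups = c("ethnicity", "quality"),
                         sensitivity = TRUE, bias = TRUE, seed = 707)
  expect_s3_class(report$overall, "pooled_result")
  expect_equal(report$overall$n_studies, 7)
  expect_false(is.null(report$bias$egger))
  expect_equal(length(report$sensitivity$results), 7)
})
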