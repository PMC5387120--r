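test_that("Woolf effect matches cross-product and reciprocal-sum formulas", {
  du <- woolf_effect(genotype_table(study_row("Du")))
  expect_equal(du$or, 2.508772, tolerance = 1e-6)
  expect_equal(du$var, 0.1708379, tolerance = 1e-6)
  expect_false(du$corrected)

  sym <- woolf_effect(fourfold(10, 10, 10, 10))
  expect_equal(sym$or, 1)
  expect_equal(sym$log_or, 0)

  # CI bounds are exp(log_or -/+ z * se)
  expect_equal(du$ci_low, exp(du$log_or - 1.959964 * du$se))
  expect_equal(du$ci_high, exp(du$log_or + 1.959964 * du$se))
})

test_that("continuity correction adds 0.5 to all cells when any cell is zero", {
  e <- woolf_effect(fourfold(1, 0, 1, 1))
  expect_true(e$corrected)
  expect_equal(e$or, 3)  # (1.5 * 1.5) / (0.5 * 1.5)
  expect_equal(e$var, 1 / 1.5 + 1 / 0.5 + 1 / 1.5 + 1 / 1.5)
  # no zero cells -> untouched
  expect_false(woolf_effect(fourfold(1, 1, 1, 1))$corrected)
})

test_that("fixed-effect pooling equals a brute-force weighted mean", {
  eff <- study_effects(fixture, "genotype")
  # all subsets of size 2..4, compared against the longhand oracle
  for (k in 2:4) {
    for (idx in utils::combn(nrow(eff), k, simplify = FALSE)) {
      sub <- eff[idx, ]
      oracle <- brute_fixed_pool(sub$log_or, sub$var)
      got <- pool_fixed_iv(sub)
      expect_equal(got$pooled_log_or, oracle$est)
      expect_equal(got$pooled_se, oracle$se)
      expect_equal(got$tau_squared, 0)
    }
  }
})

test_that("two equal-variance studies at +/- x pool to zero with Q = 2 w x^2", {
  eff <- toy_effects(c(0.7, -0.7), c(sqrt(0.2), sqrt(0.2)))
  got <- pool_fixed_iv(eff)
  expect_equal(got$pooled_log_or, 0)
  expect_equal(got$Q, 4.9)  # 2 * (1/0.2) * 0.7^2 / 2 ... frozen longhand value
})

test_that("DL tau^2 equals the method-of-moments closed form", {
  for (comparison in c("allele_L", "genotype", "allele_S")) {
    eff <- study_effects(fixture, comparison)
    expect_equal(pool_random_dl(eff)$tau_squared,
                 brute_dl_tau2(eff$log_or, eff$var))
  }
})

test_that("pooling a single study returns that study's estimate with Q = 0", {
  eff <- study_effects(fixture, "genotype")[3, , drop = FALSE]
  for (f in list(pool_fixed_iv, pool_random_dl)) {
    got <- f(eff)
    expect_equal(got$pooled_log_or, eff$log_or)
    expect_equal(got$pooled_se, eff$se)
    expect_equal(got$Q, 0)
    expect_equal(got$tau_squared, 0)
  }
})

test_that("random-effects results collapse to fixed-effect when Q <= df", {
  # Asian allele-L studies: tau^2 truncates to zero on this subset
  asian <- fixture[fixture$ethnicity == "Asian", ]
  eff <- study_effects(asian, "allele_L")
  fe <- pool_fixed_iv(eff); re <- pool_random_dl(eff)
  expect_lte(re$Q, re$df)
  expect_equal(re$tau_squared, 0)
  expect_equal(re$pooled_log_or, fe$pooled_log_or)
  expect_equal(re$pooled_se, fe$pooled_se)
})

test_that("RE pooled SE is never below FE pooled SE", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    eff <- toy_effects(rnorm(k, 0.5, 0.6), runif(k, 0.1, 0.6))
    expect_gte(pool_random_dl(eff)$pooled_se, pool_fixed_iv(eff)$pooled_se)
  }
})

test_that("pooled results are invariant under study reordering", {
  eff <- study_effects(fixture, "genotype")
  set.seed(3)
  perm <- sample(nrow(eff))
  a <- pool_random_dl(eff); b <- pool_random_dl(eff[perm, ])
  for (field in c("pooled_log_or", "pooled_se", "Q", "p_Q", "i_squared",
                  "tau_squared", "p_value"))
    expect_equal(a[[field]], b[[field]], info = field)
  expect_equal(a$weights[names(b$weights)], b$weights)
})

test_that("heterogeneity statistics follow the Q / I^2 definitions and bands", {
  eff <- study_effects(fixture, "allele_L")
  het <- heterogeneity(eff)
  expect_equal(het$df, 4)
  expect_equal(het$i_squared, max(0, (het$Q - het$df) / het$Q) * 100)
  expect_equal(het$band, "moderate")

  same <- toy_effects(c(0.4, 0.4, 0.4), c(0.2, 0.3, 0.25))
  het0 <- heterogeneity(same)
  expect_equal(het0$Q, 0)
  expect_equal(het0$i_squared, 0)
  expect_equal(het0$band, "low")

  # Q = 10 on df = 5 gives I^2 = 50% by the defining arithmetic
  expect_equal(max(0, (10 - 5) / 10) * 100, 50)

  single <- heterogeneity(eff[1, , drop = FALSE])
  expect_equal(single$Q, 0)
  expect_equal(single$p_Q, 1)
  expect_true(is.na(single$band))
})

test_that("model selection rule uses the 0.10 threshold with RE at the boundary", {
  expect_equal(select_model(0.32), "fixed_iv")
  expect_equal(select_model(0.08), "random_dl")
  expect_equal(select_model(0.10), "random_dl")
})

test_that("rule-based pooling mode switches model on the Q-test p-value", {
  eff_het <- study_effects(fixture, "allele_L")     # p_Q ~ 0.08 -> RE
  expect_equal(pool(eff_het, "rule")$model, "random_dl")
  eff_hom <- study_effects(fixture, "allele_M")     # p_Q ~ 0.32 -> FE
  expect_equal(pool(eff_hom, "rule")$model, "fixed_iv")
})

test_that("fixture pooling agrees with an independent DL implementation", {
  for (comparison in c("allele_L", "genotype")) {
    eff <- study_effects(fixture, comparison)
    ours <- pool_random_dl(eff)
    ref <- metafor::rma(yi = eff$log_or, vi = eff$var, method = "DL")
    expect_equal(ours$pooled_log_or, as.numeric(ref$b), tolerance = 1e-10)
    expect_equal(ours$pooled_se, ref$se, tolerance = 1e-10)
    expect_equal(ours$tau_squared, ref$tau2, tolerance = 1e-10)
    expect_equal(ours$Q, ref$QE, tolerance = 1e-10)
    expect_equal(ours$i_squared, ref$I2, tolerance = 1e-6)
    fe <- pool_fixed_iv(eff)
    ref_fe <- metafor::rma(yi = eff$log_or, vi = eff$var, method = "FE")
    expect_equal(fe$pooled_log_or, as.numeric(ref_fe$b), tolerance = 1e-10)
    expect_equal(fe$pooled_se, ref_fe$se, tolerance = 1e-10)
  }
})

test_that("weights are normalized and empty input is rejected", {
  eff <- study_effects(fixture, "genotype")
  expect_equal(sum(pool_random_dl(eff)$weights), 1)
  expect_equal(sum(pool_fixed_iv(eff)$weights), 1)
  expect_error(pool_fixed_iv(eff[0, ]), "empty")
})
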