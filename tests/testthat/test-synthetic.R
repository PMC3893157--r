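test_that("configuration invariants are enforced", {
  expect_error(scenario_config(prev_pop = 1.2), "prevalences")
  expect_error(scenario_config(cr_ratio = 1), "cr_ratio")
  expect_error(scenario_config(h2_liab = 1), "h2_liab")
  expect_error(scenario_config(degree_mix = c(0.5, 0.5, 0.5)), "degree_mix")
  # infeasible prevalence triple: mixture identity off by more than 0.02
  expect_error(scenario_config(cr_ratio = 0.5, prev_pop = 0.5,
                               prev_nocr = 0.3, prev_cr = 0.3),
               "mixture identity")
})

test_that("cohort structure matches the configuration", {
  cfg <- scenario_config(n = 300, cr_ratio = 0.3, prev_pop = 0.3, prev_nocr = 0.3,
                         prev_cr = 0.3, h2_liab = 0.25, n_snps = 200,
                         n_causal = 100, seed = 7)
  cc <- simulate_cohort(cfg)
  co <- cc$cohort

  # CR fraction within 1/n of the dial
  expect_lte(abs(mean(co$is_cr) - cfg$cr_ratio), 1 / cfg$n)
  # truth pairs: no self pairs, unique, expected sharing is 2^-R
  expect_false(any(cc$truth$id_a == cc$truth$id_b))
  expect_false(anyDuplicated(pair_key(cc$truth$id_a, cc$truth$id_b)) > 0)
  expect_equal(cc$truth$expected_pihat, 2^-cc$truth$degree)
  # codings as documented
  expect_true(all(co$smoking %in% 1:2))
  expect_true(all(co$alcohol %in% 1:2))
  expect_true(all(co$gender %in% 1:2))
  # affected is exactly liability > per-subpopulation threshold
  th <- attr(co, "thresholds")
  expect_identical(co$affected,
                   ifelse(co$is_cr, co$liability > th[["cr"]],
                          co$liability > th[["nocr"]]))
  # prevalence mixture identity holds for the emitted cohort
  mix <- mean(co$is_cr) * mean(co$affected[co$is_cr]) +
    (1 - mean(co$is_cr)) * mean(co$affected[!co$is_cr])
  expect_equal(mean(co$affected), mix, tolerance = 1e-12)
})

test_that("cr_ratio 0 yields an empty truth table; same seed is byte-identical", {
  cfg0 <- scenario_config(n = 100, cr_ratio = 0, n_snps = 100, n_causal = 50, seed = 3)
  expect_identical(nrow(simulate_cohort(cfg0)$truth), 0L)

  cfg <- scenario_config(n = 120, cr_ratio = 0.25, n_snps = 150, n_causal = 50, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("realized transmission sharing per degree matches 2^-R", {
  cfg <- scenario_config(n = 500, cr_ratio = 0.8, n_snps = 2000, n_causal = 100,
                         degree_mix = c(1, 1, 1) / 3, seed = 13)
  cc <- simulate_cohort(cfg)
  by_deg <- tapply(cc$truth$realized_pihat, cc$truth$degree, mean)
  expect_lt(abs(by_deg[["0"]] - 1), 0.03)
  expect_lt(abs(by_deg[["1"]] - 0.5), 0.03)
  expect_lt(abs(by_deg[["2"]] - 0.25), 0.03)
})

test_that("baseline-scenario realized prevalences hit their targets over seeds", {
  prevs <- t(sapply(1:20, function(r) {
    cfg <- scenario_config(n = 1039, cr_ratio = 0.202, prev_pop = 0.25,
                           prev_nocr = 0.26, prev_cr = 0.26, h2_liab = 0.143,
                           n_snps = 400, n_causal = 200, seed = 40 + r)
    co <- simulate_cohort(cfg)$cohort
    c(nocr = mean(co$affected[!co$is_cr]), cr = mean(co$affected[co$is_cr]),
      pop = mean(co$affected))
  }))
  expect_lt(abs(mean(prevs[, "nocr"]) - 0.26), 0.02)
  expect_lt(abs(mean(prevs[, "cr"]) - 0.26), 0.02)
  expect_lt(abs(mean(prevs[, "pop"]) - 0.25), 0.02)
})

test_that("with h2 = 0, affection is independent of relatedness", {
  # partners of affected CR individuals are affected at the CR prevalence
  partner_aff <- unlist(lapply(1:30, function(r) {
    cfg <- scenario_config(n = 200, cr_ratio = 0.5, prev_pop = 0.3, prev_nocr = 0.3,
                           prev_cr = 0.3, h2_liab = 0, n_causal = 0, n_snps = 100,
                           seed = 600 + r)
    cc <- simulate_cohort(cfg)
    co <- cc$cohort
    aff <- setNames(co$affected, co$id)
    c(aff[cc$truth$id_b][aff[cc$truth$id_a]],
      aff[cc$truth$id_a][aff[cc$truth$id_b]])
  }))
  expect_lt(abs(mean(partner_aff) - 0.3), 0.05)
})

test_that("the exposure regression recovers the generating effects", {
  cfg <- scenario_config(n = 1000, n_snps = 500, n_causal = 200, treated_rate = 0)
  truth <- cfg$betas
  hits <- sapply(1:25, function(r) {
    co <- simulate_cohort(modifyList(cfg, list(seed = 1000 + r)))$cohort
    f <- ols_fit(co$sbp, as.matrix(co[, c("bmi", "alcohol", "smoking", "age", "gender")]))
    tab <- f$coefficients
    est <- tab[, "Estimated"]
    se <- tab[, "Standard error"]
    abs(est - truth[c("intercept", "bmi", "alcohol", "smoking", "age", "gender")]) <= 2 * se
  })
  expect_gte(mean(hits), 0.90) # nominal 2-SE coverage ~95%
})
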