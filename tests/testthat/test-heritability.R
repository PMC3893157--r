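test_that("liability deviates match the normal quantile and density formulas", {
  expect_equal(threshold_deviate(0.5), 0)
  expect_equal(threshold_deviate(0.25), 0.6745, tolerance = 1e-4)
  expect_equal(threshold_deviate(0.26), 0.6433, tolerance = 1e-4)
  expect_error(threshold_deviate(0), "strictly inside")

  expect_equal(mean_liability_affected(0.5), 0.7979, tolerance = 1e-4)
  expect_equal(mean_liability_affected(0.25), 1.2711, tolerance = 1e-4)
  # whole population affected: mean deviation of the affected tends to 0
  expect_lt(mean_liability_affected(0.999), 0.01)
})

test_that("relationship weight supports both conventions", {
  expect_equal(rho_weight(0:2), 1.75)
  expect_equal(rho_weight(1), 0.5)
  expect_equal(rho_weight(1:2, "weighted_mean", weights = c(3, 1)), 0.4375)
  expect_error(rho_weight(integer(0)), "nonempty")
  expect_error(rho_weight(1:2, "weighted_mean"), "pair counts")
  expect_error(rho_weight(3), "0, 1 or 2")
})

test_that("the heritability formula reproduces direct arithmetic", {
  est <- estimate_h2_liability(
    list(mean_nocr = 0, mean_cr = -0.5, threshold = 0.8, mean_affected = 1.2711,
         sd_pheno = 1, degrees = 0:2),
    mode = "observed", rho_mode = "sum")
  # x_p = 0.8, x_q = 1.3, a_p = 1.2711, rho = 1.75
  expect_equal(est$x_p, 0.8)
  expect_equal(est$x_q, 1.3)
  expect_equal(est$h2, ((0.8 - 1.3) / 1.2711) / 1.75, tolerance = 1e-12)

  # x_p = 0.8, x_q = 0.3, a_p = 1.2711, rho = 1.75 gives 0.2248
  est2 <- estimate_h2_liability(
    list(mean_nocr = 0, mean_cr = 0.5, threshold = 0.8, mean_affected = 1.2711,
         sd_pheno = 1, degrees = 0:2),
    mode = "observed", rho_mode = "sum")
  expect_equal(est2$h2, 0.2248, tolerance = 1e-3)
})

test_that("estimator properties: antisymmetry, monotonicity, zero and flags", {
  # a more-affected CR group means a positive liability shift, hence h2 > 0
  base <- list(prev_pop = 0.25, prev_nocr = 0.2, prev_cr = 0.3, degrees = 0:2)
  e1 <- estimate_h2_liability(base)
  expect_gt(e1$h2, 0)
  flipped <- estimate_h2_liability(modifyList(base, list(prev_nocr = 0.3, prev_cr = 0.2)))
  expect_equal(e1$h2, -flipped$h2, tolerance = 1e-12)

  # equal subpopulation means give exactly zero
  e0 <- estimate_h2_liability(modifyList(base, list(prev_cr = 0.2)))
  expect_equal(e0$h2, 0)

  # decreasing in rho for a fixed positive numerator
  esum <- estimate_h2_liability(base, rho_mode = "sum")
  ew <- estimate_h2_liability(base, rho_mode = "weighted_mean",
                              weights = c(1, 1, 1))
  expect_lt(esum$rho * esum$h2 - ew$rho * ew$h2, 1e-12) # same numerator
  expect_gt(ew$h2, esum$h2)

  # out-of-range estimates are reported, flagged, never clamped
  big <- estimate_h2_liability(list(prev_pop = 0.25, prev_nocr = 0.05,
                                    prev_cr = 0.45, degrees = 2))
  expect_true(big$out_of_range)
  expect_gt(big$h2, 1)

  expect_error(estimate_h2_liability(
    list(mean_nocr = 0, mean_cr = 1, threshold = 1, mean_affected = 0,
         sd_pheno = 1, degrees = 1), mode = "observed"), "a_p = 0")
})

test_that("observed mode recovers the simulated heritability (scaled suite)", {
  est <- sapply(1:12, function(r) {
    cfg <- scenario_config(n = 1000, cr_ratio = 0.4, prev_pop = 0.25,
                           prev_nocr = 0.25, prev_cr = 0.25, h2_liab = 0.25,
                           n_snps = 600, n_causal = 300,
                           ascertainment = "affected", treated_rate = 0,
                           seed = 700 + r)
    cc <- simulate_cohort(cfg)
    inp <- falconer_inputs(cc$cohort, truth = cc$truth)
    estimate_h2_liability(inp, "observed", "weighted_mean")$h2
  })
  # per-replicate SD of this contrast is ~0.15, so the 12-seed mean has
  # SE ~0.045; a 0.1 band is a ~2 sigma check
  expect_lt(abs(mean(est) - 0.25), 0.1)
})
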