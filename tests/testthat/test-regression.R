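test_that("a noiseless linear response is fitted exactly", {
  set.seed(61)
  X <- cbind(a = rnorm(30), b = runif(30))
  y <- 2 + 3 * X[, 1] - 1.5 * X[, 2]
  f <- suppressWarnings(ols_fit(y, X)) # summary.lm warns on a perfect fit
  expect_equal(unname(coef(f)), c(2, 3, -1.5), tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
})

test_that("a 5-point bivariate fit matches the hand-solved normal equations", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  f <- ols_fit(y, cbind(x = x))
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(unname(coef(f)), c(mean(y) - slope * mean(x), slope),
               tolerance = 1e-12)
})

test_that("estimates and SEs match the normal-equations oracle (property)", {
  set.seed(62)
  for (r in 1:25) {
    n <- sample(15:60, 1)
    p <- sample(1:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    f <- ols_fit(y, X)
    o <- oracle_ols(y, X)
    expect_equal(unname(f$coefficients[, "Estimated"]), unname(o$beta),
                 tolerance = 1e-8)
    expect_equal(unname(f$coefficients[, "Standard error"]), unname(o$se),
                 tolerance = 1e-8)
    # reported invariants: t = est/se, adj R2 identity, residual df
    expect_equal(f$coefficients[, "t-value"],
                 f$coefficients[, "Estimated"] / f$coefficients[, "Standard error"])
    expect_equal(f$adj_r2, 1 - (1 - f$r2) * (n - 1) / (n - p - 1), tolerance = 1e-12)
    expect_identical(f$df_residual, as.integer(n - p - 1))
  }
})

test_that("row permutation leaves the fit unchanged", {
  set.seed(63)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("u", "v")))
  y <- 1 + X %*% c(1, -1) + rnorm(40)
  f1 <- ols_fit(y, X)
  pi <- sample(40)
  f2 <- ols_fit(y[pi], X[pi, ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-10)
})

test_that("singular designs fail loudly, naming the collinear column", {
  X <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(ols_fit(rnorm(10), X), "singular design.*b")
  expect_error(ols_fit(rnorm(3), matrix(rnorm(9), 3, 3)), "partition-size")
})

test_that("robust standard errors are available but off by default", {
  set.seed(64)
  X <- cbind(x = rnorm(200))
  y <- 1 + X[, 1] + rnorm(200, sd = abs(X[, 1]) + 0.2)
  plain <- ols_fit(y, X)
  rob <- ols_fit(y, X, robust = TRUE)
  expect_equal(coef(plain), coef(rob)) # point estimates unchanged
  expect_false(isTRUE(all.equal(plain$coefficients[, 2], rob$coefficients[, 2])))
})

test_that("treated individuals are excluded with bookkeeping", {
  co <- data.frame(id = letters[1:6], treated = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  out <- exclude_treated(co)
  expect_identical(out$id, c("b", "d", "e", "f"))
  expect_identical(attr(out, "n_removed"), 2L)
  none <- exclude_treated(data.frame(id = "x", treated = FALSE))
  expect_identical(nrow(none), 1L)
  expect_warning(exclude_treated(data.frame(id = "x", treated = TRUE)), "all individuals")
})

test_that("partition pair fits share the design and keep the bookkeeping identity", {
  cc <- simulate_cohort(scenario_config(n = 250, cr_ratio = 0.3, n_snps = 150,
                                        n_causal = 50, treated_rate = 0.2, seed = 65))
  co <- exclude_treated(cc$cohort)
  removal <- unique(c(cc$truth$id_a, cc$truth$id_b))
  fits <- fit_partition_pair(co, removal)
  expect_identical(fits$n_with - fits$n_without, sum(co$id %in% removal))
  expect_identical(rownames(fits$with_cr$coefficients),
                   rownames(fits$without_cr$coefficients))

  # empty removal: both fits identical
  same <- fit_partition_pair(co, character(0))
  expect_equal(same$with_cr$coefficients, same$without_cr$coefficients)

  expect_error(fit_partition_pair(co[, c("id", "sbp")], character(0)),
               "lacks model column")
})
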