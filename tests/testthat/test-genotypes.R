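test_that("genotype_matrix validates its invariants", {
  d <- matrix(c(0L, 1L, 2L, NA), 2, 2)
  G <- genotype_matrix(d)
  expect_s3_class(G, "genotype_matrix")
  expect_equal(dim(G), c(2L, 2L))
  expect_error(genotype_matrix(matrix(3L, 1, 1)), "0, 1, 2")
  expect_error(genotype_matrix(d, sample_ids = c("a", "a")), "duplicated")
  expect_error(genotype_matrix(d, freqs = 0.5), "length")
})

test_that("simulate_founders follows the binomial law and is deterministic", {
  # fixed frequency 1/2: dose probabilities 1/4, 1/2, 1/4
  G <- simulate_founders(4000, 1, seed = 11, freqs = 0.5)
  tab <- tabulate(G$doses + 1L, 3L) / 4000
  expect_true(all(abs(tab - c(0.25, 0.5, 0.25)) < 0.05))

  # per-SNP sample frequency concentrates around the drawn frequency
  G2 <- simulate_founders(500, 5000, maf_range = c(0.05, 0.5), seed = 12)
  phat <- colMeans(G2$doses) / 2
  expect_gte(mean(abs(phat - G2$freqs) <= 0.05), 0.95)

  # same seed twice: identical matrices
  expect_identical(simulate_founders(50, 100, seed = 3)$doses,
                   simulate_founders(50, 100, seed = 3)$doses)

  expect_error(simulate_founders(0, 10), "positive")
  expect_error(simulate_founders(10, 10, maf_range = c(0, 0.6)), "maf_range")
})

test_that("make_relative produces the requested relationship classes", {
  set.seed(21)
  G <- simulate_founders(2, 400)
  tmpl <- G$doses[1L, ]

  r0 <- make_relative(tmpl, 0)
  expect_identical(r0$genotype, as.integer(tmpl))
  expect_equal(r0$realized_pihat, 1)

  # parent-offspring: child carries at least one parental allele everywhere
  r1 <- make_relative(G$doses, 1)
  shares <- (r1$genotype >= 1L & tmpl >= 1L) | (r1$genotype <= 1L & tmpl <= 1L)
  expect_true(all(shares))
  expect_equal(r1$realized_pihat, 0.5)

  expect_error(make_relative(tmpl, 3), "degree")
  expect_error(make_relative(tmpl, 2), "freqs")
})

test_that("degree-2 realized sharing matches the labeled-allele oracle", {
  set.seed(22)
  n_pairs <- 200
  m <- 2000
  freqs <- runif(m, 0.05, 0.5)
  pkg <- replicate(n_pairs, {
    tmpl <- rbinom(m, 2L, freqs)
    make_relative(tmpl, 2, freqs = freqs)$realized_pihat
  })
  ora <- replicate(n_pairs, oracle_relative_pihat(m, 2))
  expect_lt(abs(mean(pkg) - 0.25), 0.03)
  expect_lt(abs(mean(ora) - 0.25), 0.03)
  # the package path and the independent oracle agree in distribution
  expect_lt(abs(mean(pkg) - mean(ora)), 0.01)
})

test_that("missingness filter matches a per-row count oracle", {
  set.seed(31)
  d <- matrix(sample(c(0:2, NA), 300, replace = TRUE, prob = c(.3, .3, .3, .1)),
              20, 15)
  G <- genotype_matrix(d)
  out <- filter_individuals_by_missingness(G, 0.10)
  keep_oracle <- rowSums(is.na(d)) / 15 <= 0.10
  expect_identical(rownames(out$doses), rownames(G$doses)[keep_oracle])

  # clean matrix is untouched; a 10%-missing individual is removed at 5%
  Gc <- genotype_matrix(matrix(1L, 4, 10))
  expect_identical(filter_individuals_by_missingness(Gc, 0.05)$doses, Gc$doses)
  dd <- matrix(0L, 2, 10)
  dd[2, 1] <- NA
  expect_identical(rownames(filter_individuals_by_missingness(
    genotype_matrix(dd), 0.05)$doses)[1], "S0001")
  expect_error(filter_individuals_by_missingness(genotype_matrix(matrix(NA_integer_, 2, 4)), 0.05),
               "all individuals")
})

test_that("allele frequency estimation matches a direct tally", {
  G <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1))
  expect_equal(as.numeric(allele_frequencies(G)), 0.5)
  Gm <- genotype_matrix(matrix(2L, 3, 1))
  fm <- allele_frequencies(Gm)
  expect_equal(as.numeric(fm), 1)
  expect_true(attr(fm, "monomorphic")[1])

  set.seed(32)
  d <- matrix(sample(c(0:2, NA), 600, replace = TRUE), 30, 20)
  d[, 1] <- 1L # guarantee at least one fully observed column layout
  f <- allele_frequencies(genotype_matrix(d))
  tally <- apply(d, 2, function(col) sum(col, na.rm = TRUE) / (2 * sum(!is.na(col))))
  expect_equal(unname(as.numeric(f)), unname(tally))
})
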