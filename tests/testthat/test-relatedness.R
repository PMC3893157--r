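test_that("IBS distance handles the canonical cases", {
  expect_equal(ibs_distance(c(0L, 1L, 2L), c(0L, 1L, 2L)), 1)
  expect_equal(ibs_distance(0L, 2L), 0)
  expect_equal(ibs_distance(1L, 0L), 0.5)
  expect_equal(ibs_distance(c(0L, NA), c(2L, 1L)), 0)
  expect_error(ibs_distance(NA_integer_, 1L), "undefined pair")
})

test_that("mom_ibd is symmetric and near 1 for a duplicated individual", {
  set.seed(51)
  G <- simulate_founders(50, 3000)
  freqs <- allele_frequencies(G)
  a <- G$doses[1L, ]
  dup <- mom_ibd(a, a, freqs)
  expect_gte(dup$pihat, 0.95)
  b <- G$doses[2L, ]
  ab <- mom_ibd(a, b, freqs)
  ba <- mom_ibd(b, a, freqs)
  expect_equal(ab, ba)
  # z probabilities always bounded and normalized
  expect_true(all(c(ab$z0, ab$z1, ab$z2) >= 0 & c(ab$z0, ab$z1, ab$z2) <= 1))
  expect_equal(ab$z0 + ab$z1 + ab$z2, 1, tolerance = 1e-12)
})

test_that("pairwise_relatedness agrees with the per-pair estimator", {
  set.seed(52)
  G <- simulate_founders(12, 500)
  G <- inject_missingness(G, 0.05)
  tab <- pairwise_relatedness(G, min_snps = 50)
  p <- allele_frequencies(G)
  d <- G$doses
  counts <- list(X = colSums(d, na.rm = TRUE),
                 S = 2 * colSums(!is.na(d)))
  for (r in sample(nrow(tab), 10)) {
    i <- tab$id_a[r]; j <- tab$id_b[r]
    one <- mom_ibd(d[i, ], d[j, ], as.numeric(p) , counts, min_snps = 50)
    expect_equal(tab$n_used[r], one$n_used)
    expect_equal(tab$dst[r], one$dst, tolerance = 1e-12)
    expect_equal(tab$pihat[r], one$pihat, tolerance = 1e-10)
    expect_equal(tab$z1[r], one$z1, tolerance = 1e-10)
  }
  # bounds and normalization for every pair
  expect_true(all(tab$z0 >= 0 & tab$z0 <= 1 & tab$z1 >= 0 & tab$z1 <= 1 &
                    tab$z2 >= 0 & tab$z2 <= 1))
  expect_equal(tab$z0 + tab$z1 + tab$z2, rep(1, nrow(tab)), tolerance = 1e-12)
  expect_true(all(tab$dst >= 0 & tab$dst <= 1))
  expect_true(all(tab$pihat >= 0 & tab$pihat <= 1))
})

test_that("moment IBD is calibrated per relationship degree", {
  set.seed(53)
  m <- 2000
  panel <- simulate_founders(200, m)
  freqs_true <- panel$freqs
  build_pairs <- function(degree, n_pairs) {
    pro <- simulate_founders(n_pairs, m, freqs = freqs_true)$doses
    rel <- t(sapply(seq_len(n_pairs), function(i)
      make_relative(pro[i, ], degree, freqs = freqs_true)$genotype))
    list(pro = pro, rel = rel)
  }
  p0 <- build_pairs(0, 40); p1 <- build_pairs(1, 60); p2 <- build_pairs(2, 60)
  all_doses <- rbind(panel$doses, p0$pro, p0$rel, p1$pro, p1$rel, p2$pro, p2$rel)
  rownames(all_doses) <- NULL
  Gall <- genotype_matrix(all_doses)
  p <- as.numeric(allele_frequencies(Gall))
  counts <- list(X = colSums(all_doses), S = rep(2 * nrow(all_doses), m))
  est <- function(pp) sapply(seq_len(nrow(pp$pro)), function(i)
    mom_ibd(pp$pro[i, ], pp$rel[i, ], p, counts)$pihat)
  expect_lt(abs(mean(est(p0)) - 1), 0.03)
  expect_lt(abs(mean(est(p1)) - 0.5), 0.03)
  expect_lt(abs(mean(est(p2)) - 0.25), 0.03)
  # parent-offspring pairs live almost entirely in the one-allele IBD state
  z1 <- sapply(seq_len(nrow(p1$pro)), function(i)
    mom_ibd(p1$pro[i, ], p1$rel[i, ], p, counts)$z1)
  expect_gte(mean(z1), 0.9)
  # unrelated founders: essentially no IBD. The raw moment estimator is
  # unbiased at zero; the bound-then-renormalize convention floors each
  # estimate at 0, so the mean sits at the clipped-noise level
  # E[max(N(0, sigma), 0)] ~ 0.02 at this panel size, far below the 0.25 of
  # a second-degree pair
  unrel <- sapply(1:60, function(i)
    mom_ibd(panel$doses[i, ], panel$doses[i + 60, ], p, counts)$pihat)
  expect_lte(mean(unrel), 0.04)
  expect_lt(max(unrel), 0.2) # no unrelated pair approaches the 0.25 call line
})

test_that("detection is sensitive for close pairs with a tiny false-positive rate", {
  cfg <- scenario_config(n = 400, cr_ratio = 0.5, h2_liab = 0.2, n_snps = 3000,
                         n_causal = 300, degree_mix = c(0.1, 0.9, 0),
                         prev_pop = 0.26, seed = 54)
  cc <- simulate_cohort(cfg)
  tab <- pairwise_relatedness(cc$genotypes)
  calls <- detect_cr(tab)
  truth_keys <- pair_key(cc$truth$id_a, cc$truth$id_b)
  flag_keys <- pair_key(calls$pairs$id_a, calls$pairs$id_b)
  sens <- mean(truth_keys %in% flag_keys)
  fp <- sum(!(flag_keys %in% truth_keys)) / (nrow(tab) - length(truth_keys))
  expect_gte(sens, 0.95)
  expect_lte(fp, 0.01)
})

test_that("CR calling uses a strict threshold and the union of flagged pairs", {
  tab <- data.frame(id_a = c("A", "B", "C"), id_b = c("B", "C", "D"),
                    pihat = c(0.30, 0.25, 0.10))
  calls <- detect_cr(tab, threshold = 0.25)
  expect_identical(nrow(calls$pairs), 1L) # 0.25 exactly is not flagged
  expect_identical(calls$cr_individuals, c("A", "B"))
  empty <- detect_cr(data.frame(id_a = "A", id_b = "B", pihat = 0.1))
  expect_identical(length(empty$cr_individuals), 0L)
})

test_that("pruning removes the union or a minimum vertex cover", {
  tab <- data.frame(id_a = c("A", "B"), id_b = c("B", "C"), pihat = c(0.5, 0.5))
  calls <- detect_cr(tab)
  expect_identical(prune_cr(calls, "remove_all"), c("A", "B", "C"))
  expect_identical(prune_cr(calls, "keep_one"), "B")
  expect_identical(prune_cr(detect_cr(tab[tab$pihat > 1, ]), "remove_all"),
                   character(0))

  # random graphs: cover size matches exhaustive search, and removal breaks
  # every flagged pair
  set.seed(55)
  for (r in 1:20) {
    k <- sample(4:9, 1)
    edges <- unique(t(replicate(sample(3:10, 1),
                                sort(sample(LETTERS[1:k], 2)))))
    tabr <- data.frame(id_a = edges[, 1], id_b = edges[, 2],
                       pihat = 0.6)
    cr <- detect_cr(tabr)
    cover <- prune_cr(cr, "keep_one")
    expect_identical(length(cover), oracle_min_cover_size(edges))
    expect_true(all(edges[, 1] %in% cover | edges[, 2] %in% cover))
  }
})
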