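# integer apportionment of n among proportions (largest remainder)
.apportion <- function(p, n) {
  raw <- p * n
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    o <- order(raw - k, decreasing = TRUE)
    k[o[seq_len(left)]] <- k[o[seq_len(left)]] + 1
  }
  as.integer(k)
}

# threshold between the k-th and (k+1)-th largest value so that exactly k
# values exceed it; degenerate k handled by stepping outside the range
.cut_top_k <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(Inf)
  s <- sort(x, decreasing = TRUE)
  if (k <= 0L) return(s[1L] + 1)
  if (k >= n) return(s[n] - 1)
  (s[k] + s[k + 1L]) / 2
}

#' Simulate a cohort with planted cryptic relatedness
#'
#' Generates genotypes, a quantitative blood-pressure-like trait, covariates,
#' affection status and relationship truth records under the statistical
#' structure assumed by the downstream analysis:
#' \itemize{
#'   \item Founders are unrelated Hardy-Weinberg individuals; a fraction
#'     `cr_ratio` of the cohort is replaced by relative pairs (degrees 0, 1, 2
#'     in proportions `degree_mix`) built by actual gamete dropping, so IBD
#'     estimation and liability sharing operate on the same data.
#'   \item Liability is `sqrt(h2) * g + sqrt(1 - h2) * e` on the standardized
#'     scale, where `g` is the centered, scaled polygenic score over the
#'     causal SNPs. The trait is `intercept + betas . covariates +
#'     sigma_u * liability`, with `sigma_u = sigma_e / sqrt(1 - h2)` so that
#'     the trait residual (after covariates) has heritability `h2_liab`.
#'   \item Pair probands are genetically enriched according to
#'     `config$ascertainment` (see [scenario_config()]); their relatives
#'     inherit the enrichment through transmission, which is what makes
#'     cryptic relatedness confound the trait when `h2_liab > 0`.
#'   \item Affection status is `liability > threshold` with the threshold set
#'     per subpopulation at the empirical quantile matching `prev_nocr` and
#'     `prev_cr`, making the three prevalence knobs independently
#'     controllable.
#' }
#'
#' @param config A [scenario_config()].
#' @return An object of class `cr_cohort`: a list with elements
#'   `genotypes` (a [genotype_matrix()]), `cohort` (a data frame with columns
#'   `id, sbp, bmi, smoking, alcohol, gender, age, treated, affected, is_cr,
#'   liability, liability_g`), `truth` (a data frame of planted pairs:
#'   `id_a` the proband, `id_b` the relative, `degree`, `expected_pihat`,
#'   `realized_pihat`) and `config`. Thresholds used for affection are kept
#'   in `attr(cohort, "thresholds")`.
#' @examples
#' cc <- simulate_cohort(scenario_config(n = 60, n_snps = 80, n_causal = 40))
#' table(cc$cohort$is_cr)
#' @export
simulate_cohort <- function(config) {
  validate_scenario_config(config)
  set.seed(config$seed)
  n <- config$n
  n_pairs <- round(config$cr_ratio * n / 2)
  n_cr <- 2L * n_pairs
  n_base <- n - n_cr
  deg_counts <- .apportion(config$degree_mix, n_pairs) # degrees 0,1,2
  degrees <- rep(0:2, deg_counts)
  h2 <- config$h2_liab
  h <- sqrt(h2)
  sigma_u <- config$sigma_e / sqrt(1 - h2)
  m <- config$n_snps

  freqs <- stats::runif(m, config$maf_range[1L], config$maf_range[2L])
  genetic <- config$n_causal > 0L && h2 > 0
  if (genetic) {
    causal <- sort(sample.int(m, config$n_causal))
    b <- stats::rnorm(config$n_causal)
    pc <- freqs[causal]
    var_g <- sum(2 * b^2 * pc * (1 - pc))
    mu_g <- sum(2 * b * pc)
    g_std <- function(D) (as.vector(D[, causal, drop = FALSE] %*% b) - mu_g) / sqrt(var_g)
  } else {
    causal <- integer(0)
    g_std <- function(D) rep(0, nrow(D))
  }

  draw_founders <- function(k) {
    matrix(stats::rbinom(k * m, 2L, rep(freqs, each = k)), nrow = k, ncol = m)
  }

  base_doses <- draw_founders(n_base)

  ## --- probands -------------------------------------------------------
  rho_bar <- if (n_pairs > 0) sum(deg_counts * 2^-(0:2)) / n_pairs else 0
  pro_doses <- matrix(integer(0), 0L, m)
  pro_env <- numeric(0)
  if (n_pairs > 0) {
    if (config$ascertainment == "affected") {
      # rejection-sample probands from the affected stratum of the base
      # liability distribution (threshold at the CR-free prevalence)
      t_base <- stats::qnorm(1 - config$prev_nocr)
      got <- 0L
      rows <- vector("list", 0L)
      env <- numeric(0)
      while (got < n_pairs) {
        k <- max(20L, ceiling((n_pairs - got) / config$prev_nocr * 1.3))
        cand <- draw_founders(k)
        e <- stats::rnorm(k)
        liab <- h * g_std(cand) + sqrt(1 - h2) * e
        keep <- which(liab > t_base)
        if (length(keep)) {
          take <- keep[seq_len(min(length(keep), n_pairs - got))]
          rows <- c(rows, list(cand[take, , drop = FALSE]))
          env <- c(env, e[take])
          got <- got + length(take)
        }
      }
      pro_doses <- do.call(rbind, rows)
      pro_env <- env
    } else {
      # "gap": tilt causal-allele sampling so the CR subpopulation mean
      # liability matches the shift implied by the prevalence gap under a
      # common threshold; relatives inherit rho * delta_g of the shift
      delta_target <- stats::qnorm(1 - config$prev_nocr) -
        stats::qnorm(1 - config$prev_cr)
      delta_g <- 2 * delta_target / (1 + rho_bar)
      p_tilt <- freqs[causal]
      if (!genetic || delta_g == 0) {
        if (!genetic && delta_target != 0)
          warning("prevalence gap between subpopulations cannot be realized ",
                  "genetically at h2_liab = 0; no structural shift planted")
      } else {
        target_raw <- delta_g * sqrt(var_g) / h
        pc <- freqs[causal]
        tau <- target_raw / var_g
        for (it in 1:3) {
          p_tilt <- pmin(0.98, pmax(0.02, pc + tau * b * pc * (1 - pc)))
          realized <- sum(2 * b * (p_tilt - pc))
          if (abs(realized) < 1e-12) break
          tau <- tau * target_raw / realized
        }
      }
      pro_doses <- draw_founders(n_pairs)
      if (genetic && length(causal))
        pro_doses[, causal] <- matrix(
          stats::rbinom(n_pairs * length(causal), 2L,
                        rep(p_tilt, each = n_pairs)),
          nrow = n_pairs)
      pro_env <- stats::rnorm(n_pairs)
    }
  }

  ## --- relatives ------------------------------------------------------
  rel_doses <- matrix(integer(0), 0L, m)
  realized_pihat <- numeric(n_pairs)
  if (n_pairs > 0) {
    rel_doses <- matrix(0L, n_pairs, m)
    for (i in seq_len(n_pairs)) {
      rel <- make_relative(pro_doses[i, ], degrees[i], freqs = freqs)
      rel_doses[i, ] <- rel$genotype
      realized_pihat[i] <- rel$realized_pihat
    }
  }

  ## --- assemble, shuffle, phenotype ----------------------------------
  doses <- rbind(base_doses, pro_doses, rel_doses)
  env <- c(stats::rnorm(n_base), pro_env, stats::rnorm(n_pairs))
  is_cr <- c(rep(FALSE, n_base), rep(TRUE, 2L * n_pairs))
  role <- c(rep("base", n_base), rep("proband", n_pairs), rep("relative", n_pairs))
  pair_id <- c(rep(NA_integer_, n_base), seq_len(n_pairs), seq_len(n_pairs))

  ids <- sprintf("S%04d", seq_len(n))
  perm <- sample.int(n)
  doses <- doses[perm, , drop = FALSE]
  env <- env[perm]
  is_cr <- is_cr[perm]
  role <- role[perm]
  pair_id <- pair_id[perm]
  rownames(doses) <- ids

  g <- g_std(doses)
  liability_g <- h * g
  liability <- liability_g + sqrt(1 - h2) * env

  t_nocr <- .cut_top_k(liability[!is_cr], round(config$prev_nocr * sum(!is_cr)))
  t_cr <- .cut_top_k(liability[is_cr], round(config$prev_cr * sum(is_cr)))
  affected <- ifelse(is_cr, liability > t_cr, liability > t_nocr)

  age <- stats::runif(n, 40, 79)
  bmi <- stats::rnorm(n, 23, 3)
  smoking <- 1L + stats::rbinom(n, 1L, config$smoking_rate)
  alcohol <- 1L + stats::rbinom(n, 1L, config$alcohol_rate)
  gender <- sample(1:2, n, replace = TRUE)
  treated <- stats::rbinom(n, 1L, config$treated_rate) == 1L

  be <- config$betas
  sbp <- be[["intercept"]] + be[["bmi"]] * bmi + be[["alcohol"]] * alcohol +
    be[["smoking"]] * smoking + be[["age"]] * age + be[["gender"]] * gender +
    sigma_u * liability

  cohort <- data.frame(id = ids, sbp = sbp, bmi = bmi, smoking = smoking,
                       alcohol = alcohol, gender = gender, age = age,
                       treated = treated, affected = affected, is_cr = is_cr,
                       liability = liability, liability_g = liability_g,
                       stringsAsFactors = FALSE)
  attr(cohort, "thresholds") <- c(nocr = t_nocr, cr = t_cr)

  truth <- data.frame(id_a = character(0), id_b = character(0),
                      degree = integer(0), expected_pihat = numeric(0),
                      realized_pihat = numeric(0), stringsAsFactors = FALSE)
  if (n_pairs > 0) {
    id_a <- id_b <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      id_a[i] <- ids[which(role == "proband" & pair_id == i)]
      id_b[i] <- ids[which(role == "relative" & pair_id == i)]
    }
    truth <- data.frame(id_a = id_a, id_b = id_b, degree = degrees,
                        expected_pihat = 2^-degrees,
                        realized_pihat = realized_pihat,
                        stringsAsFactors = FALSE)
  }

  G <- genotype_matrix(doses, freqs = freqs)
  if (config$missing_rate > 0) G <- inject_missingness(G, config$missing_rate)

  structure(list(genotypes = G, cohort = cohort, truth = truth,
                 config = config),
            class = "cr_cohort")
}

#' @export
print.cr_cohort <- function(x, ...) {
  cat(sprintf("cr_cohort: %d individuals, %d SNPs, %d planted pairs\n",
              nrow(x$cohort), ncol(x$genotypes$doses), nrow(x$truth)))
  cat(sprintf("  CR fraction %.3f | realized prevalences: CR-free %.3f, CR %.3f\n",
              mean(x$cohort$is_cr),
              mean(x$cohort$affected[!x$cohort$is_cr]),
              if (any(x$cohort$is_cr)) mean(x$cohort$affected[x$cohort$is_cr]) else NA))
  invisible(x)
}
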