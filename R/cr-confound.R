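#' Quantify the confounding effect of cryptic relatedness on an exposure
#' regression
#'
#' The central fitting interface of the package. Given a cohort table and
#' either genome-wide genotypes or a precomputed removal set, it
#' (1) detects cryptically related (CR) individuals from pairwise
#' method-of-moments IBD (`PI_HAT > threshold`), (2) fits the exposure
#' regression twice — on the sample with CR and on the sample with the CR
#' removal set excluded — and (3) tests the parallel-regressions hypothesis
#' that the two coefficient vectors are equal (full Chow-type F test plus
#' the per-term 1-df battery). When the cohort carries an `affected` column,
#' the heritability of liability is estimated from the prevalence contrast
#' between the two subpopulations.
#'
#' @param formula Model formula, e.g.
#'   `sbp ~ bmi + alcohol + smoking + age + gender`.
#' @param data Cohort data frame with an `id` column and the model
#'   variables; optional `treated` and `affected` logical columns.
#' @param genotypes A [genotype_matrix()] over (a superset of) the cohort
#'   ids, used to detect CR. Alternatively supply `removal` directly.
#' @param removal Character vector of ids to exclude from the CR-free fit
#'   (used when `genotypes` is absent; may be empty).
#' @param threshold PI_HAT cutoff for calling a pair cryptically related
#'   (default 1/4, strict inequality).
#' @param prune `"remove_all"` (drop every member of a flagged pair; the
#'   conventional choice) or `"keep_one"` (minimum vertex cover).
#' @param max_missing Per-individual missing-call rate above which an
#'   individual is dropped before IBD estimation.
#' @param drop_treated Drop rows with `treated == TRUE` before fitting
#'   (default `TRUE` when the column is present).
#' @return Object of class `cr_confound` with components `fits`
#'   (a `cr_partition_fits`), `chow`, `per_term`, `calls`, `pairs`,
#'   `removal`, `h2` (possibly empty), `counts` and the call. Methods:
#'   [print()], [summary()], [coef()] (two-column matrix of estimates),
#'   [predict()], [residuals()] and [plot()] (PI_HAT against IBS distance).
#' @examples
#' cc <- simulate_cohort(scenario_config(n = 80, n_snps = 300, n_causal = 100))
#' fit <- cr_confound(sbp ~ bmi + age, cc$cohort, genotypes = cc$genotypes)
#' fit
#' @export
cr_confound <- function(formula, data, genotypes = NULL, removal = NULL,
                        threshold = 0.25, prune = c("remove_all", "keep_one"),
                        max_missing = 0.05, drop_treated = TRUE) {
  prune <- match.arg(prune)
  stopifnot(is.data.frame(data))
  if (!"id" %in% names(data))
    stop("`data` must carry an `id` column of individual identifiers")
  if (is.null(genotypes) && is.null(removal))
    stop("supply either `genotypes` (to detect CR) or an explicit `removal` set")
  pairs <- NULL
  calls <- NULL
  n_filtered <- 0L
  if (!is.null(genotypes)) {
    G <- filter_individuals_by_missingness(genotypes, max_missing)
    n_filtered <- length(attr(G, "removed"))
    data <- data[data$id %in% rownames(G$doses), , drop = FALSE]
    pairs <- pairwise_relatedness(G)
    calls <- detect_cr(pairs, threshold)
    removal <- prune_cr(calls, prune)
  }
  tab <- data
  n_treated <- 0L
  if (drop_treated && "treated" %in% names(data)) {
    tab <- exclude_treated(data)
    n_treated <- attr(tab, "n_removed")
  }
  fits <- fit_partition_pair(tab, removal, formula)
  mf <- stats::model.frame(formula, tab)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)[, -1L, drop = FALSE]
  keep <- !(tab$id %in% removal)
  chow <- chow_test(y, X, y[keep], X[keep, , drop = FALSE])
  per_term <- per_term_tests(y, X, y[keep], X[keep, , drop = FALSE])

  h2 <- list()
  if ("affected" %in% names(data) && !is.null(calls)) {
    is_cr <- data$id %in% calls$cr_individuals
    pn <- mean(data$affected[!is_cr])
    pc <- if (any(is_cr)) mean(data$affected[is_cr]) else NA_real_
    deg_tab <- table(factor(calls$pairs$degree_hat, levels = 0:2))
    degrees <- as.integer(names(deg_tab))[deg_tab > 0]
    if (length(degrees) && !is.na(pc) && pc > 0 && pc < 1 && pn > 0 && pn < 1) {
      pin <- list(prev_pop = mean(data$affected), prev_nocr = pn, prev_cr = pc,
                  degrees = degrees, weights = as.integer(deg_tab)[deg_tab > 0])
      h2 <- list(prevalence_sum = estimate_h2_liability(pin, "prevalence", "sum"),
                 prevalence_weighted = estimate_h2_liability(pin, "prevalence",
                                                             "weighted_mean"))
    }
  }

  structure(list(call = match.call(), formula = formula,
                 fits = fits, chow = chow, per_term = per_term,
                 pairs = pairs, calls = calls, removal = removal,
                 h2 = h2, threshold = threshold,
                 counts = list(n_input = nrow(data),
                               n_filtered = n_filtered,
                               n_treated_removed = n_treated,
                               n_removed_cr = fits$n_removed_cr,
                               n_with = fits$n_with,
                               n_without = fits$n_without)),
            class = "cr_confound")
}

#' @export
print.cr_confound <- function(x, ...) {
  cat("Cryptic-relatedness confounding analysis\n")
  cat(sprintf("  samples: with CR n = %d | without CR n = %d (removed %d CR, %d treated)\n",
              x$counts$n_with, x$counts$n_without,
              x$counts$n_removed_cr, x$counts$n_treated_removed))
  if (!is.null(x$calls))
    cat(sprintf("  detected %d pair(s) with PI_HAT > %g (%d individuals)\n",
                nrow(x$calls$pairs), x$threshold, length(x$calls$cr_individuals)))
  cat(sprintf("  parallel regressions: F = %.3f (df %d, %d), p = %.4g\n",
              x$chow$statistic, x$chow$parameter[1L], x$chow$parameter[2L],
              x$chow$p.value))
  invisible(x)
}

#' @export
summary.cr_confound <- function(object, ...) {
  structure(object, class = c("summary.cr_confound", class(object)))
}

#' @export
print.summary.cr_confound <- function(x, ...) {
  print.cr_confound(x)
  cat("\n")
  print(x$fits)
  cat("\nPer-term parallel-regressions tests:\n")
  print(x$per_term, row.names = FALSE)
  if (length(x$h2)) {
    cat("\n")
    for (h in x$h2) if (!is.null(h)) print(h)
  }
  invisible(x)
}

#' @export
coef.cr_confound <- function(object, ...) {
  cbind(with_cr = coef(object$fits$with_cr),
        without_cr = coef(object$fits$without_cr))
}

#' @export
predict.cr_confound <- function(object, newdata = NULL,
                                which = c("with_cr", "without_cr"), ...) {
  which <- match.arg(which)
  predict(object$fits[[which]], newdata = newdata, ...)
}

#' @export
residuals.cr_confound <- function(object,
                                  which = c("with_cr", "without_cr"), ...) {
  which <- match.arg(which)
  residuals(object$fits[[which]])
}

#' Plot PI_HAT against IBS distance for every pair
#'
#' The diagnostic scatter used to visualize a cohort's relatedness
#' structure: each point is an unordered pair, flagged pairs (PI_HAT above
#' the threshold) are highlighted, and the calling threshold is drawn as a
#' horizontal line.
#'
#' @param x A `cr_confound` object fitted with genotypes, or a `cr_pairs`
#'   data frame.
#' @param threshold PI_HAT cutoff line (taken from the object if present).
#' @param ... Passed to [graphics::plot()].
#' @return The input, invisibly.
#' @export
plot.cr_confound <- function(x, threshold = x$threshold, ...) {
  if (is.null(x$pairs)) stop("object was fitted without genotypes; nothing to plot")
  plot.cr_pairs(x$pairs, threshold = threshold, ...)
  invisible(x)
}

#' @rdname plot.cr_confound
#' @export
plot.cr_pairs <- function(x, threshold = 0.25, ...) {
  flagged <- x$pihat > threshold
  graphics::plot(x$dst, x$pihat, xlab = "IBS distance", ylab = "IBD probability (PI_HAT)",
                 pch = 20, col = ifelse(flagged, "firebrick", "grey40"),
                 ylim = c(0, 1), ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}
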