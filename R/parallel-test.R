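# residual sum of squares of an OLS fit on a (possibly stacked) design
.rss <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop("degenerate test: stacked design is rank deficient")
  sum(fit$residuals^2)
}

#' Chow-type test of the parallel-regressions hypothesis
#'
#' Tests whether regression coefficients are equal across two samples
#' (null: `b_1 = b_2` for the tested terms) by comparing the restricted
#' model (common coefficients throughout) against an unrestricted model in
#' which the tested terms receive group-specific coefficients, built through
#' group-interaction columns on the stacked data:
#' `F = [(SSR_restricted - SSR_unrestricted) / q] / [SSR_unrestricted / df]`
#' with `q` the number of constrained terms and `df` the unrestricted
#' residual degrees of freedom. With `tested_terms = "all"` this is the
#' classic full Chow test; a single term gives the 1-df slope-equality
#' test, whose F equals the square of the two-sample coefficient-difference
#' t statistic.
#'
#' @param y1,y2 Response vectors of the two groups.
#' @param X1,X2 Predictor matrices sharing the same column specification
#'   (intercept added internally; do not include one).
#' @param tested_terms `"all"`, or a character subset of
#'   `c("(Intercept)", colnames(X1))` to constrain.
#' @return Object of classes `chow_test` and `htest` with the F statistic,
#'   numerator/denominator degrees of freedom, p value, the tested terms
#'   and both residual sums of squares.
#' @examples
#' x <- rnorm(50); y <- 1 + 2 * x + rnorm(50)
#' x2 <- rnorm(50); y2 <- 1 + 2 * x2 + rnorm(50)
#' chow_test(y, cbind(x = x), y2, cbind(x = x2))
#' @export
chow_test <- function(y1, X1, y2, X2, tested_terms = "all") {
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  if (ncol(X1) > 0L && is.null(colnames(X1)))
    colnames(X1) <- paste0("x", seq_len(ncol(X1)))
  if (ncol(X2) > 0L && is.null(colnames(X2))) colnames(X2) <- colnames(X1)
  if (ncol(X1) != ncol(X2) || !identical(colnames(X1), colnames(X2)))
    stop("the two designs must share an identical column specification")
  stopifnot(length(y1) == nrow(X1), length(y2) == nrow(X2))
  terms_all <- c("(Intercept)", colnames(X1))
  if (identical(tested_terms, "all")) tested_terms <- terms_all
  if (!all(tested_terms %in% terms_all))
    stop("unknown tested term(s): ",
         paste(setdiff(tested_terms, terms_all), collapse = ", "))
  y <- c(y1, y2)
  g <- rep(c(0, 1), c(length(y1), length(y2)))
  Xc <- cbind(`(Intercept)` = 1, rbind(X1, X2))
  inter <- Xc[, tested_terms, drop = FALSE] * g
  colnames(inter) <- paste0(tested_terms, ":group2")
  Xu <- cbind(Xc, inter)
  q <- length(tested_terms)
  df_den <- length(y) - ncol(Xu)
  if (df_den <= 0)
    stop("degenerate test: no residual degrees of freedom in the unrestricted model")
  ssr_r <- .rss(y, Xc)
  ssr_u <- .rss(y, Xu)
  if (ssr_u <= .Machine$double.eps * sum(y^2))
    stop("degenerate test: unrestricted model has (near-)zero residual variance")
  f <- ((ssr_r - ssr_u) / q) / (ssr_u / df_den)
  f <- max(f, 0) # guard tiny negative round-off
  structure(list(statistic = c(F = f),
                 parameter = c(num_df = q, den_df = df_den),
                 p.value = stats::pf(f, q, df_den, lower.tail = FALSE),
                 method = "Chow-type test of parallel regressions",
                 data.name = sprintf("two samples (n1 = %d, n2 = %d)",
                                     length(y1), length(y2)),
                 tested_terms = tested_terms,
                 ssr_restricted = ssr_r,
                 ssr_unrestricted = ssr_u),
            class = c("chow_test", "htest"))
}

#' Per-coefficient 1-df parallel-regressions tests
#'
#' Runs [chow_test()] once per coefficient (intercept included), each time
#' constraining only that term, and returns the battery as a data frame.
#' The per-term 1-df reporting is the closest match to published single-F
#' summaries of regression-equality tests; p values are unadjusted for
#' multiplicity, as in that reporting convention.
#'
#' @inheritParams chow_test
#' @return Data frame with columns `term, f_value, df_num, df_den, p_value`,
#'   carrying the individual `chow_test` objects in the `"tests"` attribute.
#' @export
per_term_tests <- function(y1, X1, y2, X2) {
  X1 <- as.matrix(X1)
  if (ncol(X1) > 0L && is.null(colnames(X1)))
    colnames(X1) <- paste0("x", seq_len(ncol(X1)))
  terms_all <- c("(Intercept)", colnames(X1))
  tests <- lapply(terms_all, function(tm) chow_test(y1, X1, y2, X2, tested_terms = tm))
  out <- data.frame(term = terms_all,
                    f_value = vapply(tests, function(t) unname(t$statistic), 0),
                    df_num = vapply(tests, function(t) unname(t$parameter[1L]), 0),
                    df_den = vapply(tests, function(t) unname(t$parameter[2L]), 0),
                    p_value = vapply(tests, function(t) t$p.value, 0),
                    stringsAsFactors = FALSE)
  attr(out, "tests") <- tests
  out
}
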