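#' Ordinary least-squares fit with full coefficient inference
#'
#' Fits `y` on a design matrix by OLS (through [stats::lm()]) and returns
#' the coefficient table in the conventional reporting layout: estimate,
#' standard error from the unbiased residual-variance estimate, t value and
#' two-sided p value on the residual degrees of freedom, together with the
#' residual sum of squares, R-squared and adjusted R-squared. A
#' rank-deficient design raises an error naming the collinear columns
#' rather than silently dropping them.
#'
#' @param y Numeric response vector.
#' @param X Numeric design matrix of predictors; an intercept column (named
#'   `(Intercept)`, or any constant column) is added if absent.
#' @param labels Optional column labels overriding `colnames(X)`.
#' @param robust When `TRUE`, replace the classical standard errors by
#'   heteroskedasticity-consistent (HC1) sandwich standard errors. Off by
#'   default: the point of the analysis is what naive OLS reports when
#'   relatedness-induced dependence is ignored.
#' @return Object of class `cr_ols`: list with `coefficients` (matrix with
#'   columns `Estimated`, `Standard error`, `t-value`, `Pr(>|t|)`), `rss`,
#'   `df_residual`, `r2`, `adj_r2`, `sigma`, `n` and the underlying `lm`
#'   fit.
#' @examples
#' X <- cbind(x1 = rnorm(20), x2 = rnorm(20))
#' f <- ols_fit(3 + 2 * X[, 1] + rnorm(20), X)
#' coef(f)
#' @export
ols_fit <- function(y, X, labels = NULL, robust = FALSE) {
  X <- as.matrix(X)
  if (!is.null(labels)) colnames(X) <- labels
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  has_int <- any(apply(X, 2L, function(col) all(col == col[1L])))
  if (has_int) {
    ic <- which(apply(X, 2L, function(col) all(col == col[1L])))[1L]
    X <- X[, -ic, drop = FALSE]
  }
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L)
    stop(sprintf("partition-size error: n = %d individuals cannot support %d predictors",
                 n, p))
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  tab <- sm$coefficients
  if (robust) {
    Xi <- stats::model.matrix(fit)
    e <- stats::residuals(fit)
    bread <- chol2inv(chol(crossprod(Xi)))
    meat <- crossprod(Xi * e)
    vc <- bread %*% meat %*% bread * n / (n - ncol(Xi)) # HC1
    se <- sqrt(diag(vc))
    tab[, 2L] <- se
    tab[, 3L] <- tab[, 1L] / se
    tab[, 4L] <- 2 * stats::pt(abs(tab[, 3L]), fit$df.residual, lower.tail = FALSE)
  }
  colnames(tab) <- c("Estimated", "Standard error", "t-value", "Pr(>|t|)")
  rownames(tab) <- c("(Intercept)", colnames(X))
  structure(list(coefficients = tab,
                 rss = sum(stats::residuals(fit)^2),
                 df_residual = fit$df.residual,
                 r2 = sm$r.squared,
                 adj_r2 = sm$adj.r.squared,
                 sigma = sm$sigma,
                 n = n,
                 lm = fit),
            class = "cr_ols")
}

#' @export
print.cr_ols <- function(x, digits = 4, ...) {
  cat(sprintf("OLS fit: n = %d, adjusted R-squared = %.2f\n", x$n, x$adj_r2))
  stats::printCoefmat(x$coefficients, digits = digits, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.cr_ols <- function(object, ...) object$coefficients[, "Estimated"]

#' @export
predict.cr_ols <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  stats::predict(object$lm, newdata = as.data.frame(newdata), ...)
}

#' @export
residuals.cr_ols <- function(object, ...) stats::residuals(object$lm)

#' Write a coefficient table as TSV
#'
#' @param fit A `cr_ols` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_coef_table <- function(fit, path) {
  stopifnot(inherits(fit, "cr_ols"))
  tab <- data.frame(term = rownames(fit$coefficients), fit$coefficients,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop individuals medically treated for the outcome
#'
#' Removes rows with `treated == TRUE` before regression, since treatment
#' masks the untreated trait value; the number removed is recorded in the
#' `"n_removed"` attribute.
#'
#' @param cohort Cohort data frame with a logical `treated` column.
#' @return Filtered data frame (with a warning if nothing survives).
#' @export
exclude_treated <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (!"treated" %in% names(cohort)) stop("`treated` column missing from cohort table")
  keep <- !cohort$treated
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("all individuals are flagged as treated")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Fit the exposure regression on samples with and without cryptic relatives
#'
#' Fits the same design twice: on every retained individual (the sample
#' *with* CR) and on the sample left after additionally dropping the removal
#' set (the sample *without* CR). Covariates with the `{1, 2}` codings enter
#' untransformed as numeric, mirroring the conventional reporting. Rows with
#' missing values in the model variables are dropped (complete-case) with
#' the counts recorded.
#'
#' @param cohort Cohort data frame (typically after [exclude_treated()]).
#' @param removal Character vector of ids to exclude from the second fit
#'   (e.g. from [prune_cr()]).
#' @param formula Model formula; default
#'   `sbp ~ bmi + alcohol + smoking + age + gender`.
#' @return Object of class `cr_partition_fits`: list with `with_cr` and
#'   `without_cr` (both `cr_ols`), `n_with`, `n_without`, `n_removed_cr`,
#'   `n_incomplete` and the `formula`.
#' @export
fit_partition_pair <- function(cohort, removal = character(0),
                               formula = sbp ~ bmi + alcohol + smoking + age + gender) {
  stopifnot(is.data.frame(cohort))
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(cohort))
  if (length(miss))
    stop("cohort table lacks model column(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(cohort[, vars, drop = FALSE])
  n_incomplete <- sum(!cc)
  dat <- cohort[cc, , drop = FALSE]
  build <- function(d) {
    mf <- stats::model.frame(formula, d)
    list(y = stats::model.response(mf),
         X = stats::model.matrix(formula, mf)[, -1L, drop = FALSE])
  }
  a <- build(dat)
  fit_with <- ols_fit(a$y, a$X)
  keep <- !(dat$id %in% removal)
  b <- build(dat[keep, , drop = FALSE])
  fit_without <- ols_fit(b$y, b$X)
  structure(list(with_cr = fit_with, without_cr = fit_without,
                 n_with = fit_with$n, n_without = fit_without$n,
                 n_removed_cr = sum(!keep), n_incomplete = n_incomplete,
                 formula = formula),
            class = "cr_partition_fits")
}

#' @export
print.cr_partition_fits <- function(x, ...) {
  cat(sprintf("Sample with CR (n = %d), adjusted R-squared = %.2f\n",
              x$n_with, x$with_cr$adj_r2))
  stats::printCoefmat(x$with_cr$coefficients, digits = 4, has.Pvalue = TRUE)
  cat(sprintf("\nSample without CR (n = %d), adjusted R-squared = %.2f\n",
              x$n_without, x$without_cr$adj_r2))
  stats::printCoefmat(x$without_cr$coefficients, digits = 4, has.Pvalue = TRUE)
  invisible(x)
}
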