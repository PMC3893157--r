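#' Normal-liability threshold deviate
#'
#' Position of the affection threshold on the standard-normal liability
#' scale, measured from the group mean, for a group with prevalence `K`:
#' the upper-tail quantile `qnorm(1 - K)`.
#'
#' @param K Prevalence in `(0, 1)`.
#' @return Threshold deviate (vectorized over `K`).
#' @examples
#' threshold_deviate(0.25) # 0.6745
#' @export
threshold_deviate <- function(K) {
  if (any(K <= 0 | K >= 1)) stop("prevalence must lie strictly inside (0, 1)")
  stats::qnorm(1 - K)
}

#' Mean liability of affected individuals
#'
#' Mean deviation of the affected (above-threshold) group from its
#' population mean on the standard-normal liability scale:
#' `a = dnorm(x) / K` with `x` the threshold deviate. Tends to 0 as the
#' whole population becomes affected.
#'
#' @param K Prevalence in `(0, 1)`.
#' @return Mean liability deviation of the affected (vectorized).
#' @examples
#' mean_liability_affected(0.25) # 1.2711
#' @export
mean_liability_affected <- function(K) {
  dev <- threshold_deviate(K)
  stats::dnorm(dev) / K
}

#' Relationship weight over the detected degrees of relatedness
#'
#' The expected proportion of the genome shared IBD is `2^-R` for
#' relationship degree `R`. With a mixture of degrees among the detected
#' pairs, `sum` mode returns the literal sum of `2^-R` over the degrees
#' present (the convention of the source analysis, which exceeds 1 when all
#' of degrees 0-2 are present), while `weighted_mean` returns the pair-count
#' weighted average — the statistically conventional choice, reported
#' alongside the sum by the pipeline.
#'
#' @param degrees_present Nonempty subset of `c(0, 1, 2)`.
#' @param mode `"sum"` or `"weighted_mean"`.
#' @param weights Pair counts per degree (required for `weighted_mean`).
#' @return The relationship weight `rho`.
#' @examples
#' rho_weight(0:2) # 1.75
#' rho_weight(1:2, "weighted_mean", weights = c(3, 1)) # 0.4375
#' @export
rho_weight <- function(degrees_present, mode = c("sum", "weighted_mean"),
                       weights = NULL) {
  mode <- match.arg(mode)
  if (length(degrees_present) == 0L)
    stop("`degrees_present` must be a nonempty subset of {0, 1, 2}")
  if (!all(degrees_present %in% 0:2)) stop("degrees must be 0, 1 or 2")
  if (anyDuplicated(degrees_present)) stop("degrees must be distinct")
  r <- 2^-degrees_present
  if (mode == "sum") return(sum(r))
  if (is.null(weights) || length(weights) != length(degrees_present) ||
      any(weights < 0) || sum(weights) == 0)
    stop("`weighted_mean` mode requires nonnegative pair counts per degree")
  sum(weights * r) / sum(weights)
}

#' Heritability of liability from prevalence or observed-scale contrasts
#'
#' Falconer-type estimator `h2 = ((x_p - x_q) / a_p) / rho` comparing the
#' CR-free subpopulation (p) with the cryptically related subpopulation (q):
#' \describe{
#'   \item{prevalence mode}{the deviates are derived from the three
#'     prevalences on the standard-normal liability scale:
#'     `x_p = threshold_deviate(prev_nocr)`, `x_q = threshold_deviate(prev_cr)`
#'     and `a_p = mean_liability_affected(prev_pop)`, so that `x_p - x_q`
#'     equals the standardized mean-liability shift of the CR group.}
#'   \item{observed mode}{the deviates are built from phenotype-scale
#'     quantities standardized by the phenotypic SD:
#'     `x_p = (threshold - mean_nocr) / sd`, `x_q = (threshold - mean_cr) / sd`,
#'     `a_p = (mean_affected - mean_nocr) / sd` (the threshold cancels from
#'     the numerator). See [falconer_inputs()] for assembling these from a
#'     cohort table.}
#' }
#' The relationship weight `rho` is computed with [rho_weight()] from the
#' degrees present among the detected pairs. Estimates outside `[0, 1]` are
#' reported with an `out_of_range` flag, never clamped.
#'
#' @param inputs Named list. Prevalence mode requires `prev_pop`,
#'   `prev_nocr`, `prev_cr`; observed mode requires `mean_nocr`, `mean_cr`,
#'   `threshold`, `mean_affected`, `sd_pheno`. Either may carry `degrees`
#'   and `weights` (pair counts) used for `rho`.
#' @param mode `"prevalence"` or `"observed"`.
#' @param rho_mode Passed to [rho_weight()].
#' @param degrees,weights Override the degree set and pair counts in
#'   `inputs`.
#' @return Object of class `h2_estimate`: list with `h2`, `x_p`, `x_q`,
#'   `a_p`, `rho`, `mode`, `rho_mode`, `out_of_range`.
#' @examples
#' estimate_h2_liability(list(prev_pop = 0.25, prev_nocr = 0.30,
#'                            prev_cr = 0.22, degrees = 0:2))
#' @export
estimate_h2_liability <- function(inputs, mode = c("prevalence", "observed"),
                                  rho_mode = c("sum", "weighted_mean"),
                                  degrees = inputs$degrees,
                                  weights = inputs$weights) {
  mode <- match.arg(mode)
  rho_mode <- match.arg(rho_mode)
  if (is.null(degrees)) stop("`degrees` (the degrees of relationship present) is required")
  rho <- rho_weight(degrees, rho_mode, weights)
  if (mode == "prevalence") {
    need <- c("prev_pop", "prev_nocr", "prev_cr")
    if (!all(need %in% names(inputs)))
      stop("prevalence mode requires inputs: ", paste(need, collapse = ", "))
    x_p <- threshold_deviate(inputs$prev_nocr)
    x_q <- threshold_deviate(inputs$prev_cr)
    a_p <- mean_liability_affected(inputs$prev_pop)
  } else {
    need <- c("mean_nocr", "mean_cr", "threshold", "mean_affected", "sd_pheno")
    if (!all(need %in% names(inputs)))
      stop("observed mode requires inputs: ", paste(need, collapse = ", "))
    if (inputs$sd_pheno <= 0) stop("`sd_pheno` must be positive")
    x_p <- (inputs$threshold - inputs$mean_nocr) / inputs$sd_pheno
    x_q <- (inputs$threshold - inputs$mean_cr) / inputs$sd_pheno
    a_p <- (inputs$mean_affected - inputs$mean_nocr) / inputs$sd_pheno
  }
  if (a_p == 0) stop("degenerate input: a_p = 0")
  if (rho == 0) stop("degenerate input: rho = 0")
  h2 <- ((x_p - x_q) / a_p) / rho
  structure(list(h2 = h2, x_p = x_p, x_q = x_q, a_p = a_p, rho = rho,
                 mode = mode, rho_mode = rho_mode,
                 out_of_range = h2 < 0 || h2 > 1),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("Heritability of liability (%s mode, rho = %.4f [%s]):\n",
              x$mode, x$rho, x$rho_mode))
  cat(sprintf("  h2 = %.4f%s   (x_p = %.4f, x_q = %.4f, a_p = %.4f)\n",
              x$h2, if (x$out_of_range) " [outside [0,1]]" else "",
              x$x_p, x$x_q, x$a_p))
  invisible(x)
}

#' Observed-scale heritability inputs from a cohort table
#'
#' Assembles the phenotype-scale quantities consumed by
#' [estimate_h2_liability()]'s observed mode from a cohort table and a CR
#' partition: the mean trait in the CR-free subpopulation, the mean in the
#' CR group, the trait value marking the affection threshold (the empirical
#' CR-free quantile at its prevalence), the mean among affected CR-free
#' individuals and the CR-free phenotypic SD. When a relationship truth
#' table is supplied the CR contrast group is the pairs' second members
#' (the relatives of the ascertained probands — the configuration under
#' which the Falconer contrast is unbiased); otherwise the whole detected CR
#' set is used, which mixes probands with relatives and is reported as such.
#'
#' @param cohort Cohort data frame (columns `sbp`, `affected`, `is_cr`,
#'   `id`).
#' @param truth Optional relationship truth table from [simulate_cohort()]
#'   (columns `id_a`, `id_b`, `degree`).
#' @param cr_ids Character vector of CR individual ids (used when `truth` is
#'   absent, e.g. from [detect_cr()]).
#' @param degrees,weights Degree set and pair counts for the relationship
#'   weight; derived from `truth` when available.
#' @return Named list ready to pass to [estimate_h2_liability()].
#' @export
falconer_inputs <- function(cohort, truth = NULL, cr_ids = NULL,
                            degrees = NULL, weights = NULL) {
  stopifnot(is.data.frame(cohort),
            all(c("id", "sbp", "affected", "is_cr") %in% names(cohort)))
  base <- cohort[!cohort$is_cr, , drop = FALSE]
  if (nrow(base) < 2L) stop("CR-free subpopulation too small")
  if (!is.null(truth) && nrow(truth)) {
    grp <- cohort$sbp[cohort$id %in% truth$id_b]
    if (is.null(degrees)) {
      tab <- table(factor(truth$degree, levels = 0:2))
      degrees <- as.integer(names(tab))[tab > 0]
      weights <- as.integer(tab)[tab > 0]
    }
  } else {
    if (is.null(cr_ids)) stop("supply either `truth` or `cr_ids`")
    grp <- cohort$sbp[cohort$id %in% cr_ids]
  }
  if (!length(grp)) stop("empty CR contrast group")
  prev <- mean(base$affected)
  if (prev <= 0 || prev >= 1)
    stop("CR-free subpopulation must contain both affected and unaffected individuals")
  list(mean_nocr = mean(base$sbp),
       mean_cr = mean(grp),
       threshold = as.numeric(stats::quantile(base$sbp, 1 - prev)),
       mean_affected = mean(base$sbp[base$affected]),
       sd_pheno = stats::sd(base$sbp),
       degrees = degrees, weights = weights)
}
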