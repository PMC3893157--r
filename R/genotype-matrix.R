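#' Genotype matrix of allele doses
#'
#' Container for biallelic SNP genotypes coded as reference-allele doses
#' (0, 1, 2, or `NA` for a missing call), one row per individual, one column
#' per SNP, optionally carrying per-SNP reference-allele frequencies.
#'
#' @param doses Integer matrix of allele doses in `{0, 1, 2, NA}`; row and
#'   column names, when absent, are generated from `sample_ids` / `snp_ids`.
#' @param sample_ids Character vector of unique individual identifiers.
#' @param snp_ids Character vector of unique SNP identifiers.
#' @param freqs Optional numeric vector of per-SNP reference-allele
#'   frequencies (e.g. the generating frequencies of a simulation). Estimated
#'   frequencies are obtained with [allele_frequencies()].
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `doses` (named integer matrix) and `freqs` (numeric or `NULL`).
#' @examples
#' G <- genotype_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2))
#' allele_frequencies(G)
#' @export
genotype_matrix <- function(doses, sample_ids = rownames(doses),
                            snp_ids = colnames(doses), freqs = NULL) {
  doses <- as.matrix(doses)
  storage.mode(doses) <- "integer"
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(doses)))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%05d", seq_len(ncol(doses)))
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != nrow(doses))
    stop("`sample_ids` length must equal the number of rows of `doses`")
  if (length(snp_ids) != ncol(doses))
    stop("`snp_ids` length must equal the number of columns of `doses`")
  if (anyDuplicated(sample_ids)) stop("duplicated sample identifiers")
  if (anyDuplicated(snp_ids)) stop("duplicated SNP identifiers")
  bad <- doses[!is.na(doses)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("non-missing doses must lie in {0, 1, 2}")
  if (!is.null(freqs)) {
    freqs <- as.numeric(freqs)
    if (length(freqs) != ncol(doses))
      stop("`freqs` length must equal the number of SNPs")
  }
  dimnames(doses) <- list(sample_ids, snp_ids)
  structure(list(doses = doses, freqs = freqs), class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$doses)

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x$doses)
  miss <- mean(is.na(x$doses))
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.2f%% missing calls)\n",
              d[1L], d[2L], 100 * miss))
  cat(if (is.null(x$freqs)) "reference-allele frequencies: not set\n"
      else "reference-allele frequencies: attached\n")
  invisible(x)
}

#' Sample identifiers of a genotype matrix
#' @param G A [genotype_matrix()].
#' @return Character vector of individual ids.
#' @export
sample_ids <- function(G) rownames(G$doses)

#' Estimate per-SNP reference-allele frequencies
#'
#' Frequencies are the mean dose over non-missing calls divided by two.
#' SNPs that are monomorphic in the data (estimated frequency 0 or 1) are
#' flagged through the `"monomorphic"` attribute; such SNPs carry no
#' information for moment-based IBD estimation and are excluded there.
#'
#' @param G A [genotype_matrix()].
#' @return Numeric vector of frequencies named by SNP id, with a logical
#'   attribute `"monomorphic"`.
#' @export
allele_frequencies <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  n_obs <- colSums(!is.na(G$doses))
  if (any(n_obs == 0L))
    stop("SNP(s) with zero non-missing calls: ",
         paste(colnames(G$doses)[n_obs == 0L][seq_len(min(5L, sum(n_obs == 0L)))],
               collapse = ", "))
  p <- colMeans(G$doses, na.rm = TRUE) / 2
  attr(p, "monomorphic") <- p <= 0 | p >= 1
  p
}

#' Per-individual missing-call rates
#' @param G A [genotype_matrix()].
#' @return Numeric vector, one rate per individual.
#' @export
missing_rates <- function(G) rowMeans(is.na(G$doses))

#' Remove individuals with a high missing-call rate
#'
#' Mirrors the standard per-individual genotyping quality filter applied
#' before pairwise relatedness estimation: individuals whose fraction of
#' missing calls exceeds `max_missing_rate` are dropped; row order of the
#' survivors is preserved.
#'
#' @param G A [genotype_matrix()].
#' @param max_missing_rate Maximum tolerated missing-call fraction in
#'   `[0, 1]` (default 0.05).
#' @return A filtered `genotype_matrix` with attribute `"removed"` holding
#'   the ids of the removed individuals.
#' @export
filter_individuals_by_missingness <- function(G, max_missing_rate = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!is.numeric(max_missing_rate) || length(max_missing_rate) != 1L ||
      is.na(max_missing_rate) || max_missing_rate < 0 || max_missing_rate > 1)
    stop("`max_missing_rate` must be a single value in [0, 1]")
  keep <- missing_rates(G) <= max_missing_rate
  if (!any(keep))
    stop("all individuals removed by the missingness filter (rate ",
         max_missing_rate, ")")
  out <- genotype_matrix(G$doses[keep, , drop = FALSE], freqs = G$freqs)
  attr(out, "removed") <- rownames(G$doses)[!keep]
  out
}

#' Inject missing calls uniformly at random
#'
#' Sets each call to missing independently with probability `rate`, using the
#' current RNG state. Used to exercise missingness filters on simulated data.
#'
#' @param G A [genotype_matrix()].
#' @param rate Per-call missingness probability in `[0, 1)`.
#' @return A `genotype_matrix` with missing calls injected.
#' @export
inject_missingness <- function(G, rate) {
  stopifnot(inherits(G, "genotype_matrix"), rate >= 0, rate < 1)
  if (rate == 0) return(G)
  d <- G$doses
  d[stats::runif(length(d)) < rate] <- NA_integer_
  genotype_matrix(d, freqs = G$freqs)
}
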