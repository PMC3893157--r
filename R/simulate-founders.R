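#' Simulate unrelated founder genotypes under Hardy-Weinberg equilibrium
#'
#' Per-SNP reference-allele frequencies are drawn uniformly from `maf_range`
#' (unless supplied through `freqs`) and doses are drawn as two independent
#' binomial allele draws per individual and SNP; SNPs are unlinked.
#'
#' @param n_founders Number of individuals (>= 1).
#' @param n_snps Number of SNPs (>= 1).
#' @param maf_range Length-2 interval inside `(0, 0.5]` from which per-SNP
#'   frequencies are drawn (default `c(0.05, 0.5)`).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (so the function composes with an enclosing `set.seed()`).
#' @param freqs Optional vector of per-SNP frequencies overriding the draw.
#' @return A [genotype_matrix()] with the generating frequencies attached.
#' @examples
#' G <- simulate_founders(10, 50, seed = 1)
#' @export
simulate_founders <- function(n_founders, n_snps, maf_range = c(0.05, 0.5),
                              seed = NULL, freqs = NULL) {
  if (!is.numeric(n_founders) || n_founders < 1 || n_founders != round(n_founders))
    stop("`n_founders` must be a positive integer")
  if (!is.numeric(n_snps) || n_snps < 1 || n_snps != round(n_snps))
    stop("`n_snps` must be a positive integer")
  if (is.null(freqs)) {
    if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
        maf_range[1L] > maf_range[2L])
      stop("`maf_range` must be an interval inside (0, 0.5]")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freqs)) freqs <- stats::runif(n_snps, maf_range[1L], maf_range[2L])
  stopifnot(length(freqs) == n_snps)
  doses <- matrix(stats::rbinom(n_founders * n_snps, 2L, rep(freqs, each = n_founders)),
                  nrow = n_founders, ncol = n_snps)
  genotype_matrix(doses, freqs = freqs)
}

# one gamete per SNP from a dose vector; heterozygous sites transmit a
# uniformly chosen allele
.gamete <- function(dose) {
  g <- dose / 2
  het <- which(dose == 1L)
  g[het] <- stats::rbinom(length(het), 1L, 0.5)
  as.integer(g)
}

#' Mendelian offspring of two genotype rows
#'
#' Transmits one uniformly chosen allele per SNP from each parent
#' (gamete dropping at unlinked loci). Missing parental calls propagate as
#' missing in the child.
#'
#' @param a,b Integer dose vectors of the two parents.
#' @return Integer dose vector of the offspring.
#' @export
offspring <- function(a, b) {
  stopifnot(length(a) == length(b))
  out <- .gamete(a) + .gamete(b)
  out[is.na(a) | is.na(b)] <- NA_integer_
  as.integer(out)
}

#' Create a relative of a template individual by gamete dropping
#'
#' Builds a new individual related to the first row of `parents` at the
#' requested degree:
#' \describe{
#'   \item{degree 0}{an exact genotype copy (monozygotic-twin-like duplicate).}
#'   \item{degree 1}{a parent-offspring relative: child of the template and a
#'     mate (second row of `parents` if given, otherwise a founder simulated
#'     from `freqs`). Full sibs, the other first-degree class with the same
#'     expected sharing, can be built with two [offspring()] calls.}
#'   \item{degree 2}{a grandchild, produced by two generations of gamete
#'     dropping through an unobserved intermediate child; half-sibs and
#'     avuncular pairs share the same expected genome fraction.}
#' }
#' The realized proportion of the genome shared identical by descent with the
#' template is tracked exactly from the transmission path: 1 for degree 0,
#' 1/2 for parent-offspring, and half the fraction of loci at which the
#' intermediate transmitted the template-derived allele for degree 2.
#'
#' @param parents Integer dose vector of the template individual, or a matrix
#'   whose first row is the template (a second row, if present, is the mate
#'   used for degree 1).
#' @param degree Relationship degree, one of 0, 1, 2.
#' @param freqs Per-SNP reference-allele frequencies used to simulate
#'   unobserved mates (required for degree 2, and for degree 1 when no mate
#'   row is supplied).
#' @param seed Optional integer seed.
#' @return List with elements `genotype` (integer dose vector), `degree`,
#'   `expected_pihat` (`2^-degree`) and `realized_pihat`.
#' @export
make_relative <- function(parents, degree, freqs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(parents)) {
    template <- as.integer(parents[1L, ])
    mate <- if (nrow(parents) >= 2L) as.integer(parents[2L, ]) else NULL
  } else {
    template <- as.integer(parents)
    mate <- NULL
  }
  if (!is.numeric(degree) || length(degree) != 1L || !(degree %in% 0:2))
    stop("`degree` must be 0, 1 or 2")
  m <- length(template)
  sim_mate <- function() {
    if (is.null(freqs)) stop("`freqs` required to simulate an unobserved mate")
    stopifnot(length(freqs) == m)
    stats::rbinom(m, 2L, freqs)
  }
  if (degree == 0) {
    geno <- template
    realized <- 1
  } else if (degree == 1) {
    if (is.null(mate)) mate <- sim_mate()
    geno <- offspring(template, mate)
    realized <- 0.5
  } else {
    # grandparent-grandchild: child = template x mate1; the child transmits
    # its template-derived allele with probability 1/2 per locus
    mate1 <- sim_mate()
    mate2 <- sim_mate()
    from_template <- .gamete(template)
    from_mate1 <- .gamete(mate1)
    path <- stats::rbinom(m, 1L, 0.5) # 1 = grandparental allele transmitted
    transmitted <- ifelse(path == 1L, from_template, from_mate1)
    geno <- as.integer(transmitted + .gamete(mate2))
    geno[is.na(template)] <- NA_integer_
    realized <- mean(path) / 2
  }
  list(genotype = geno, degree = as.integer(degree),
       expected_pihat = 2^-degree, realized_pihat = realized)
}
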