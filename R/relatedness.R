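# Expected per-SNP IBS-state probabilities conditional on sharing 0/1/2
# alleles IBD. With sample allele counts available the polynomial terms are
# replaced by their unbiased factorial-moment estimators (counts X of the
# reference allele and Y of the alternate out of S = X + Y observed
# alleles); with frequencies only, the plug-in Hardy-Weinberg polynomials
# are used. Returns a list of per-SNP vectors e0_z0, e1_z0, e2_z0, e1_z1,
# e2_z1 (and e2_z2 = 1 implicitly).
.ibd_expectations <- function(freqs, allele_counts = NULL) {
  p <- freqs
  q <- 1 - p
  if (is.null(allele_counts)) {
    p2q2 <- p^2 * q^2
    p3q <- p^3 * q
    pq3 <- p * q^3
    p4 <- p^4
    q4 <- q^4
    pq <- p * q
    p3 <- p^3
    q3 <- q^3
  } else {
    S <- allele_counts$S
    X <- allele_counts$X
    Y <- S - X
    d4 <- S * (S - 1) * (S - 2) * (S - 3)
    d3 <- S * (S - 1) * (S - 2)
    d2 <- S * (S - 1)
    p2q2 <- X * (X - 1) * Y * (Y - 1) / d4
    p3q <- X * (X - 1) * (X - 2) * Y / d4
    pq3 <- X * Y * (Y - 1) * (Y - 2) / d4
    p4 <- X * (X - 1) * (X - 2) * (X - 3) / d4
    q4 <- Y * (Y - 1) * (Y - 2) * (Y - 3) / d4
    pq <- X * Y / d2
    p3 <- X * (X - 1) * (X - 2) / d3
    q3 <- Y * (Y - 1) * (Y - 2) / d3
  }
  list(e0_z0 = 2 * p2q2,
       e1_z0 = 4 * p3q + 4 * pq3,
       e2_z0 = p4 + q4 + 4 * p2q2,
       e1_z1 = 2 * pq,
       e2_z1 = p3 + q3 + pq)
}

# Solve the moment equations for (z0, z1, z2) given observed IBS-state
# counts and summed expected state counts; out-of-range estimates are
# bounded to [0, 1] and renormalized to sum to one.
.solve_ibd <- function(i0, i1, i2, E0z0, E1z0, E2z0, E1z1, E2z1, n_used) {
  z0 <- i0 / E0z0
  z1 <- (i1 - z0 * E1z0) / E1z1
  z2 <- (i2 - z0 * E2z0 - z1 * E2z1) / n_used
  z0 <- pmin(1, pmax(0, z0))
  z1 <- pmin(1, pmax(0, z1))
  z2 <- pmin(1, pmax(0, z2))
  s <- z0 + z1 + z2
  s[s == 0] <- 1
  list(z0 = z0 / s, z1 = z1 / s, z2 = z2 / s)
}

#' Identity-by-state distance between two genotype rows
#'
#' `dst = (IBS2 + 0.5 * IBS1) / n_used`, the mean fraction of alleles shared
#' identical in state over the SNPs non-missing in both individuals;
#' identical rows give 1, opposite homozygotes give 0.
#'
#' @param a,b Integer dose vectors.
#' @return A single number in `[0, 1]`.
#' @export
ibs_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("undefined pair: no SNP observed in both individuals")
  1 - sum(abs(a[ok] - b[ok])) / (2 * sum(ok))
}

#' Method-of-moments IBD estimation for one pair
#'
#' Estimates the probabilities of sharing 0, 1 or 2 alleles identical by
#' descent (Z0, Z1, Z2) from the observed identity-by-state profile of a
#' pair, given panel allele frequencies, and summarizes them as
#' `PI_HAT = Z2 + Z1 / 2`. Monomorphic SNPs carry no information and are
#' excluded. Out-of-range moment estimates are bounded to `[0, 1]` and
#' renormalized.
#'
#' @param a,b Integer dose vectors of the two individuals.
#' @param freqs Per-SNP reference-allele frequencies estimated on the same
#'   panel (see [allele_frequencies()]).
#' @param allele_counts Optional list with per-SNP observed allele counts
#'   `X` (reference) and `S` (total); when supplied, expected IBS-state
#'   probabilities use finite-sample-corrected (factorial-moment)
#'   estimators, as when called through [pairwise_relatedness()].
#' @param min_snps Pairs with fewer informative overlapping SNPs than this
#'   floor are flagged `low_confidence` (default 100).
#' @return One-row data frame with columns `n_used, dst, z0, z1, z2, pihat,
#'   low_confidence`.
#' @export
mom_ibd <- function(a, b, freqs, allele_counts = NULL, min_snps = 100) {
  stopifnot(length(a) == length(b), length(freqs) == length(a))
  poly <- freqs > 0 & freqs < 1 & !is.na(freqs)
  ok <- poly & !is.na(a) & !is.na(b)
  n_used <- sum(ok)
  if (n_used == 0L) stop("undefined pair: no informative SNP observed in both individuals")
  aa <- a[ok]; bb <- b[ok]
  # |dose difference| 2 = opposite homozygotes (IBS0), 0 = identical (IBS2)
  ibs0 <- sum(abs(aa - bb) == 2L)
  ibs2 <- sum(aa == bb)
  ibs1 <- n_used - ibs2 - ibs0
  e <- .ibd_expectations(freqs[ok],
                         if (is.null(allele_counts)) NULL
                         else list(X = allele_counts$X[ok], S = allele_counts$S[ok]))
  z <- .solve_ibd(ibs0, ibs1, ibs2,
                  sum(e$e0_z0), sum(e$e1_z0), sum(e$e2_z0),
                  sum(e$e1_z1), sum(e$e2_z1), n_used)
  data.frame(n_used = n_used,
             dst = (ibs2 + 0.5 * ibs1) / n_used,
             z0 = z$z0, z1 = z$z1, z2 = z$z2,
             pihat = z$z2 + z$z1 / 2,
             low_confidence = n_used < min_snps)
}

#' All-pairs IBS distance and method-of-moments IBD estimation
#'
#' Computes, for every unordered pair of retained individuals, the count of
#' SNPs observed in both, the IBS distance, the moment estimates of the IBD
#' state probabilities (Z0, Z1, Z2) and `PI_HAT = Z2 + Z1 / 2`. Allele
#' frequencies default to estimates from the full retained sample (relatives
#' included — a known small bias source) and expected IBS-state
#' probabilities use finite-sample-corrected estimators based on the
#' observed allele counts. The IBS-state tallies are computed by dense
#' indicator-matrix cross products, so genome-wide panels over a few
#' thousand individuals remain tractable.
#'
#' @param G A [genotype_matrix()].
#' @param freqs Optional frequency vector overriding the panel estimate
#'   (disables the finite-sample correction).
#' @param min_snps Floor on informative overlapping SNPs below which a pair
#'   is flagged `low_confidence` rather than silently reported.
#' @param snp_subsample Optional number of SNPs to subsample uniformly at
#'   random before estimation (an LD-thinning stand-in; default uses all).
#' @return A data frame of class `cr_pairs` with columns `id_a, id_b,
#'   n_used, dst, z0, z1, z2, pihat, low_confidence`, one row per unordered
#'   pair (`id_a` precedes `id_b` in sample order).
#' @examples
#' G <- simulate_founders(8, 300, seed = 4)
#' head(pairwise_relatedness(G))
#' @export
pairwise_relatedness <- function(G, freqs = NULL, min_snps = 100,
                                 snp_subsample = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$doses
  if (nrow(d) < 2L) stop("need at least two individuals")
  if (!is.null(snp_subsample) && snp_subsample < ncol(d))
    d <- d[, sort(sample.int(ncol(d), snp_subsample)), drop = FALSE]
  use_counts <- is.null(freqs)
  if (use_counts) {
    Gsub <- genotype_matrix(d)
    p <- allele_frequencies(Gsub)
    mono <- attr(p, "monomorphic")
  } else {
    stopifnot(length(freqs) == ncol(d))
    p <- freqs
    mono <- p <= 0 | p >= 1
  }
  keep <- !mono & !is.na(p)
  d <- d[, keep, drop = FALSE]
  p <- as.numeric(p[keep])
  n <- nrow(d)
  m <- ncol(d)
  if (m == 0L) stop("no polymorphic SNPs available for IBD estimation")

  has_na <- anyNA(d)
  d0 <- d
  if (has_na) d0[is.na(d0)] <- -1L
  A0 <- (d0 == 0L) * 1
  A1 <- (d0 == 1L) * 1
  A2 <- (d0 == 2L) * 1
  IBS2 <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  C02 <- tcrossprod(A0, A2)
  IBS0 <- C02 + t(C02)
  if (has_na) {
    B <- (d0 >= 0L) * 1
    Nused <- tcrossprod(B)
  } else {
    B <- NULL
    Nused <- matrix(m, n, n)
  }
  IBS1 <- Nused - IBS2 - IBS0

  counts <- if (use_counts) {
    nobs <- colSums(d0 >= 0L)
    list(X = colSums(pmax(d0, 0L)), S = 2 * nobs)
  } else NULL
  e <- .ibd_expectations(p, counts)
  if (has_na) {
    Ee <- lapply(e, function(v) B %*% (t(B) * v))
  } else {
    Ee <- lapply(e, function(v) matrix(sum(v), n, n))
  }

  lo <- lower.tri(IBS2)
  z <- .solve_ibd(IBS0[lo], IBS1[lo], IBS2[lo],
                  Ee$e0_z0[lo], Ee$e1_z0[lo], Ee$e2_z0[lo],
                  Ee$e1_z1[lo], Ee$e2_z1[lo], Nused[lo])
  idx <- which(lo, arr.ind = TRUE) # row > col: id_a = col (earlier), id_b = row
  ids <- rownames(d)
  nu <- Nused[lo]
  out <- data.frame(id_a = ids[idx[, 2L]], id_b = ids[idx[, 1L]],
                    n_used = nu,
                    dst = (IBS2[lo] + 0.5 * IBS1[lo]) / nu,
                    z0 = z$z0, z1 = z$z1, z2 = z$z2,
                    pihat = z$z2 + z$z1 / 2,
                    low_confidence = nu < min_snps,
                    stringsAsFactors = FALSE)
  if (any(nu == 0))
    stop("undefined pair(s) with zero overlapping informative SNPs")
  class(out) <- c("cr_pairs", "data.frame")
  out
}

#' Write a pairwise relatedness report
#'
#' Tab-separated layout mirroring the conventional pairwise `.genome`
#' report: `id_a, id_b, n_used, dst, z0, z1, z2, pihat, flagged`.
#'
#' @param pairs A `cr_pairs` data frame from [pairwise_relatedness()].
#' @param path Output path.
#' @param threshold PI_HAT cutoff used to fill the `flagged` column.
#' @return The path, invisibly.
#' @export
write_pair_report <- function(pairs, path, threshold = 0.25) {
  stopifnot(inherits(pairs, "data.frame"))
  out <- pairs[, c("id_a", "id_b", "n_used", "dst", "z0", "z1", "z2", "pihat")]
  out$flagged <- pairs$pihat > threshold
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call cryptic relatedness from a pairwise table
#'
#' Flags pairs whose estimated proportion of the genome shared IBD exceeds
#' the threshold (strictly: `PI_HAT > threshold`, a pair at exactly the
#' cutoff is not called), and collects the set of individuals appearing in
#' any flagged pair. A coarse degree classification is attached per flagged
#' pair from standard PI_HAT bins (> 0.75: degree 0; (0.354, 0.75]:
#' degree 1; otherwise degree 2).
#'
#' @param pairs A `cr_pairs` data frame from [pairwise_relatedness()].
#' @param threshold PI_HAT cutoff, default 1/4.
#' @return An object of class `cr_calls`: list with `threshold`, `pairs`
#'   (the flagged subset plus a `degree_hat` column) and `cr_individuals`.
#' @export
detect_cr <- function(pairs, threshold = 0.25) {
  stopifnot(inherits(pairs, "data.frame"),
            all(c("id_a", "id_b", "pihat") %in% names(pairs)))
  flagged <- pairs[pairs$pihat > threshold, , drop = FALSE]
  if (nrow(flagged)) {
    flagged$degree_hat <- ifelse(flagged$pihat > 0.75, 0L,
                                 ifelse(flagged$pihat > 2^-1.5, 1L, 2L))
  } else flagged$degree_hat <- integer(0)
  structure(list(threshold = threshold,
                 pairs = flagged,
                 cr_individuals = sort(unique(c(flagged$id_a, flagged$id_b)))),
            class = "cr_calls")
}

#' @export
print.cr_calls <- function(x, ...) {
  cat(sprintf("cr_calls: %d pair(s) with PI_HAT > %g involving %d individual(s)\n",
              nrow(x$pairs), x$threshold, length(x$cr_individuals)))
  if (nrow(x$pairs))
    print(table(degree_hat = x$pairs$degree_hat))
  invisible(x)
}

# exact minimum vertex cover by edge branching (components are small);
# edges: 2-column character matrix
.min_vertex_cover <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  best <- unique(c(edges)) # trivial cover
  recurse <- function(edges, chosen) {
    if (length(chosen) >= length(best)) return()
    if (nrow(edges) == 0L) {
      best <<- chosen
      return()
    }
    u <- edges[1L, 1L]; v <- edges[1L, 2L]
    for (w in c(u, v)) {
      rest <- edges[edges[, 1L] != w & edges[, 2L] != w, , drop = FALSE]
      recurse(rest, c(chosen, w))
    }
  }
  recurse(edges, character(0))
  best
}

#' Choose individuals to remove for a relatedness-free sample
#'
#' `remove_all` removes every individual involved in a flagged pair (the
#' conventional conservative choice). `keep_one` instead removes a minimum
#' vertex cover of the flagged-pair graph, i.e. the smallest set whose
#' removal leaves no flagged pair intact, retaining as many individuals as
#' possible; components are solved exactly up to 24 vertices and by a
#' max-degree greedy heuristic beyond that.
#'
#' @param calls A `cr_calls` object from [detect_cr()].
#' @param mode `"remove_all"` (default) or `"keep_one"`.
#' @return Character vector of sample ids to remove.
#' @export
prune_cr <- function(calls, mode = c("remove_all", "keep_one")) {
  stopifnot(inherits(calls, "cr_calls"))
  mode <- match.arg(mode)
  if (mode == "remove_all" || nrow(calls$pairs) == 0L)
    return(calls$cr_individuals)
  edges <- cbind(calls$pairs$id_a, calls$pairs$id_b)
  # connected components by union-find with path halving
  verts <- unique(c(edges))
  parent <- seq_along(verts)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(edges[, 1L], verts)
  ib <- match(edges[, 2L], verts)
  for (e in seq_len(nrow(edges))) {
    ra <- find(ia[e]); rb <- find(ib[e])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_along(verts), find, 0L)
  removal <- character(0)
  for (cid in unique(comp)) {
    vs <- verts[comp == cid]
    sub <- edges[edges[, 1L] %in% vs, , drop = FALSE]
    if (length(vs) <= 24L) {
      removal <- c(removal, .min_vertex_cover(sub))
    } else {
      while (nrow(sub) > 0L) { # greedy max-degree fallback
        tab <- sort(table(c(sub)), decreasing = TRUE)
        w <- names(tab)[1L]
        removal <- c(removal, w)
        sub <- sub[sub[, 1L] != w & sub[, 2L] != w, , drop = FALSE]
      }
    }
  }
  sort(removal)
}
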