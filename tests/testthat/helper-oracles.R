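# Independent oracles used across the suite. These deliberately do not call
# the package's own construction paths.

# Labeled-allele gamete-dropping oracle: every founder allele carries a
# unique integer label, transmission picks one parental label per locus, and
# the realized kinship of a pair is read off the shared labels directly.
oracle_relative_pihat <- function(m, degree) {
  counter <- 0L
  founder <- function() {
    h <- matrix(counter + seq_len(2L * m), nrow = 2L)
    counter <<- counter + 2L * m
    h
  }
  gam <- function(h) h[cbind(sample(1:2, m, replace = TRUE), seq_len(m))]
  child <- function(pa, pb) rbind(gam(pa), gam(pb))
  A <- founder()
  B <- if (degree == 0) A
  else if (degree == 1) child(A, founder())
  else child(child(A, founder()), founder())
  shared <- vapply(seq_len(m), function(j) length(intersect(A[, j], B[, j])), 0L)
  mean(shared) / 2
}

# Brute-force normal-equations OLS: estimates and classical standard errors.
oracle_ols <- function(y, X) {
  X1 <- cbind(1, X)
  xtx_inv <- solve(t(X1) %*% X1)
  beta <- drop(xtx_inv %*% t(X1) %*% y)
  res <- y - drop(X1 %*% beta)
  df <- length(y) - ncol(X1)
  sigma2 <- sum(res^2) / df
  list(beta = beta, se = sqrt(diag(xtx_inv) * sigma2), rss = sum(res^2), df = df)
}

# Exhaustive minimum vertex cover over all vertex subsets (tiny graphs only).
oracle_min_cover_size <- function(edges) {
  verts <- unique(c(edges))
  k <- length(verts)
  best <- k
  for (mask in 0:(2^k - 1)) {
    inset <- verts[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    covered <- all(edges[, 1] %in% inset | edges[, 2] %in% inset)
    if (covered) best <- min(best, length(inset))
  }
  best
}

# Full Chow F from three separate OLS fits (pooled vs per-group).
oracle_full_chow <- function(y1, X1, y2, X2) {
  r1 <- oracle_ols(y1, X1)
  r2 <- oracle_ols(y2, X2)
  rp <- oracle_ols(c(y1, y2), rbind(X1, X2))
  q <- ncol(X1) + 1
  dfd <- length(y1) + length(y2) - 2 * q
  f <- ((rp$rss - r1$rss - r2$rss) / q) / ((r1$rss + r2$rss) / dfd)
  list(f = f, df = c(q, dfd), p = pf(f, q, dfd, lower.tail = FALSE))
}

# Convenience: canonical unordered-pair keys.
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
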