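# Independent oracles used across the suite.  These deliberately use
# different algorithms (dense linear algebra, exhaustive enumeration) from
# the package implementations they check.

# Sample variance and type-7 percentile straight from their definitions.
oracle_variance <- function(x) sum((x - sum(x) / length(x))^2) / (length(x) - 1)
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# GLS fixed effects by dense inversion of V = s2e I + s2u Z Z'
oracle_gls <- function(y, X, Z, s2u, s2e) {
  V <- s2e * diag(length(y)) + s2u * tcrossprod(Z)
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# VanRaden relationship matrix written out literally
oracle_vanraden <- function(M) {
  p <- colMeans(M) / 2
  W <- sweep(M, 2, 2 * p)
  (W %*% t(W)) / (2 * sum(p * (1 - p)))
}

# brute-force average-linkage clustering cut at height h: repeatedly merge
# the pair of clusters with the smallest mean pairwise distance while that
# mean is <= h
oracle_avg_linkage <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq(i + 1, length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  memb
}

# exhaustive best-subset AIC over all 2^p candidate models
oracle_best_subset_aic <- function(y, X) {
  p <- ncol(X)
  best_aic <- stats::AIC(stats::lm(y ~ 1))
  for (k in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(k, 2^(seq_len(p) - 1)) > 0)
    a <- stats::AIC(stats::lm(y ~ X[, idx, drop = FALSE]))
    if (a < best_aic) best_aic <- a
  }
  best_aic
}

# set partition equality irrespective of labels
same_partition <- function(a, b) {
  identical(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min,
                                                numeric(1)))],
            split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min,
                                                numeric(1)))])
}
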