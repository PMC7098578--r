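#' Restricted maximum likelihood for a single variance component
#'
#' Fits the linear mixed model `y = X b + u + e` with `u ~ N(0, s2u * A)` and
#' `e ~ N(0, s2e * I)` by profiling the REML log-likelihood over the single
#' variance ratio `gamma = s2u / s2e`.  The covariance structure `A` is
#' eigen-decomposed once, after which each evaluation of the profiled
#' objective is O(n), so the one-dimensional optimisation is cheap even for
#' panels of several hundred individuals.
#'
#' The random term can be given either as a grouping factor/indicator matrix
#' `Z` (in which case `A = Z Z'` and BLUPs are returned per level of `Z`) or
#' directly as a covariance matrix `A` (e.g. a genomic relationship matrix).
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (must include the intercept column).
#' @param Z optional indicator matrix (n x q) for a grouping random effect.
#' @param A optional n x n covariance structure; exactly one of `Z`, `A`.
#' @param tol convergence tolerance on the profiled objective.
#' @param gamma_bounds search interval for the variance ratio.
#' @return list with elements `beta` (fixed effects), `vcov_beta`, `s2u`,
#'   `s2e`, `gamma`, `blup` (per level of `Z`, or the n-vector `u_hat` when
#'   `A` was supplied), `fitted`, `loglik` (profiled restricted
#'   log-likelihood, up to a constant), `at_bound` (TRUE when the ratio hit
#'   the search boundary, i.e. the component was truncated at ~0 or the
#'   residual variance vanished), and the eigen pieces `U`, `d` for reuse.
#' @keywords internal
reml_onecomp <- function(y, X, Z = NULL, A = NULL, tol = 1e-8,
                         gamma_bounds = c(1e-10, 1e10)) {
  if (is.null(A) == is.null(Z))
    stop("supply exactly one of 'Z' or 'A'")
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) must match length(y)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    stop("fixed-effect design is rank deficient; aliased columns: ",
         paste(dropped, collapse = ", "))
  }
  p <- ncol(X)

  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    A <- tcrossprod(Z)
  }
  eA <- eigen(A, symmetric = TRUE)
  d <- pmax(eA$values, 0)
  U <- eA$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  profile <- function(lg) {
    g <- exp(lg)
    w <- 1 / (1 + g * d)
    Xw <- Xt * w
    XtVX <- crossprod(Xt, Xw)
    b <- solve(XtVX, crossprod(Xw, yt))
    r <- yt - Xt %*% b
    rss <- sum(w * r * r)
    # saturated fixed part (n == p) leaves no residual df: the ratio is
    # unidentified and the GLS solution is exact whatever gamma
    s2e <- if (n > p) max(rss / (n - p), .Machine$double.xmin)
           else .Machine$double.xmin
    obj <- 0.5 * (sum(log1p(g * d)) +
                    (if (n > p) (n - p) * log(s2e) else 0) +
                    as.numeric(determinant(XtVX, logarithm = TRUE)$modulus))
    list(obj = obj, b = b, w = w, s2e = s2e, XtVX = XtVX, r = r)
  }

  lo <- log(gamma_bounds[1]); hi <- log(gamma_bounds[2])
  opt <- stats::optimize(function(lg) profile(lg)$obj, c(lo, hi), tol = tol)
  at_bound <- (opt$minimum - lo) < 1e-4 || (hi - opt$minimum) < 1e-4
  # snap to an exact zero component when the ratio collapsed onto the floor
  gamma <- exp(opt$minimum)
  if ((opt$minimum - lo) < 1e-4) gamma <- 0
  fit <- profile(log(max(gamma, gamma_bounds[1])))
  if (gamma == 0) fit <- profile(lo)

  s2e <- fit$s2e
  s2u <- gamma * s2e
  beta <- drop(fit$b)
  names(beta) <- colnames(X)
  vcov_beta <- s2e * solve(fit$XtVX)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  wr <- fit$w * fit$r
  if (!is.null(Z)) {
    blup <- gamma * drop(crossprod(Z, U %*% wr))
    names(blup) <- colnames(Z)
  } else {
    blup <- gamma * drop(A %*% (U %*% wr))
  }
  fitted <- drop(X %*% beta) + if (!is.null(Z)) drop(Z %*% blup) else blup

  list(beta = beta, vcov_beta = vcov_beta, s2u = s2u, s2e = s2e,
       gamma = gamma, blup = blup, fitted = fitted,
       loglik = -fit$obj, at_bound = at_bound, U = U, d = d)
}

#' Indicator matrix for a factor
#' @keywords internal
indicator_matrix <- function(f) {
  f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}
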