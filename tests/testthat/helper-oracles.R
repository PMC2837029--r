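# Independent reference implementations used as oracles. These stay
# deliberately naive (lm loops, optim, dense matrix products) and never
# share code with the package internals they check.

# brute force componentwise base fit: all p univariate lm fits, argmin RSS
oracle_componentwise <- function(u, X) {
  rss <- slope <- intercept <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    fit <- lm(u ~ X[, j])
    rss[j] <- sum(residuals(fit)^2)
    slope[j] <- coef(fit)[2L]
    intercept[j] <- coef(fit)[1L]
  }
  j <- which.min(rss)
  list(j_star = j, slope = slope[j], intercept = intercept[j],
       rss = rss[j])
}

# logistic MLE by direct BFGS maximization of the binomial log-likelihood
oracle_logistic_mle <- function(Z, y1) {
  D <- cbind(1, Z)
  nll <- function(b) {
    eta <- drop(D %*% b)
    -sum(y1 * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    eta <- drop(D %*% b)
    -drop(crossprod(D, y1 - plogis(eta)))
  }
  opt <- optim(rep(0, ncol(D)), nll, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  opt$par
}

# dense accumulation of the boosting hat operator along a given selection
# sequence: B_m = B_{m-1} + nu * H_{j_m} %*% (I - B_{m-1}) with explicit
# n x n matrix products; returns trace path (df) including df(0) = 0
oracle_df_dense <- function(W, sel, nu) {
  n <- nrow(W)
  mu <- colMeans(W)
  Bm <- matrix(0, n, n)
  df <- numeric(length(sel) + 1L)
  for (m in seq_along(sel)) {
    j <- sel[m]
    xc <- W[, j] - mu[j]
    ssq <- sum(xc^2)
    H <- matrix(1 / n, n, n)
    if (ssq > 0) H <- H + tcrossprod(xc) / ssq
    Bm <- Bm + nu * H %*% (diag(n) - Bm)
    df[m + 1L] <- sum(diag(Bm))
  }
  df
}

# small seeded Gaussian fixture
make_toy <- function(n, p, seed, signal = 0) {
  set.seed(seed)
  y <- rep(c(-1L, 1L), length.out = n)[sample.int(n)]
  X <- matrix(rnorm(n * p), n, p)
  if (signal > 0) X[y == 1L, 1L] <- X[y == 1L, 1L] + signal
  list(X = X, y = y)
}

# exact two-sided binomial band: smallest interval [lo, hi] of rejection
# counts with >= conf coverage around rate under n trials
binomial_band <- function(n, rate, conf = 0.99) {
  a <- (1 - conf) / 2
  c(lo = qbinom(a, n, rate) / n, hi = qbinom(1 - a, n, rate) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
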