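# named settings of the Gaussian two-group-shift simulation design:
# (p_star, mu_X, mu_Z, duplicate_xz)
.sim_settings <- list(
  null = list(p_star = 0,   mu_X = 0,   mu_Z = 0, duplicate_xz = FALSE),
  a    = list(p_star = 5,   mu_X = 0.5, mu_Z = 0, duplicate_xz = FALSE),
  b    = list(p_star = 5,   mu_X = 0.8, mu_Z = 0, duplicate_xz = FALSE),
  c    = list(p_star = 50,  mu_X = 0.3, mu_Z = 0, duplicate_xz = FALSE),
  d    = list(p_star = 50,  mu_X = 0.5, mu_Z = 0, duplicate_xz = FALSE),
  e    = list(p_star = 200, mu_X = 0.3, mu_Z = 0, duplicate_xz = FALSE),
  f1   = list(p_star = 5,   mu_X = 1,   mu_Z = 1, duplicate_xz = FALSE),
  f2   = list(p_star = 5,   mu_X = 1,   mu_Z = 1, duplicate_xz = TRUE)
)

#' Simulation setting for the two-group Gaussian shift design
#'
#' Bundles the parameters of the synthetic-data generator. The named
#' settings lock `(p_star, mu_X, mu_Z)` to the benchmark design: a binary
#' outcome drawn fair-coin, informative molecular columns shifted by
#' `mu_X` in the `Y = +1` group, clinical columns shifted by `mu_Z`, all
#' with unit variance. Settings: `null` (p* = 0), `a` (5, 0.5), `b`
#' (5, 0.8), `c` (50, 0.3), `d` (50, 0.5), `e` (200, 0.3); `f1` and `f2`
#' make both blocks informative (`mu_Z = mu_X = 1`), with `f2`
#' additionally copying the informative molecular columns verbatim from
#' the clinical columns (`X_1 = Z_1, ..., X_q = Z_q`) so the molecular
#' block is fully redundant.
#'
#' @param name one of `"null"`, `"a"`–`"e"`, `"f1"`, `"f2"`, `"custom"`.
#' @param n,p,q sample size, molecular and clinical dimension (defaults
#'   100, 1000, 5 — the benchmark scale).
#' @param p_star,mu_X,mu_Z,duplicate_xz free parameters for
#'   `name = "custom"`; ignored (locked) for named settings.
#' @param shuffle randomly permute the column order of X (informative
#'   columns come first by construction; shuffling verifies
#'   order-invariance of downstream analyses).
#' @return An object of class `sim_setting`.
#' @export
sim_setting <- function(name = c("null", "a", "b", "c", "d", "e",
                                 "f1", "f2", "custom"),
                        n = 100, p = 1000, q = 5,
                        p_star = 0, mu_X = 0, mu_Z = 0,
                        duplicate_xz = FALSE, shuffle = FALSE) {
  name <- match.arg(name)
  if (name != "custom") {
    s <- .sim_settings[[name]]
    p_star <- s$p_star; mu_X <- s$mu_X; mu_Z <- s$mu_Z
    duplicate_xz <- s$duplicate_xz
  }
  if (p_star < 0 || p_star > p) stop("p_star must be in [0, p]")
  if (duplicate_xz && p_star != q)
    stop("duplicate_xz requires p_star = q (molecular copies of all ",
         "clinical columns)")
  if (q > p) stop("q must not exceed p when duplicating")
  structure(list(name = name, n = as.integer(n), p = as.integer(p),
                 q = as.integer(q), p_star = as.integer(p_star),
                 mu_X = mu_X, mu_Z = mu_Z, duplicate_xz = duplicate_xz,
                 shuffle = shuffle),
            class = "sim_setting")
}

#' @export
print.sim_setting <- function(x, ...) {
  cat(sprintf(
    "Simulation setting \"%s\": n = %d, p = %d, q = %d, p* = %d, ",
    x$name, x$n, x$p, x$q, x$p_star))
  cat(sprintf("mu_X = %g, mu_Z = %g%s\n", x$mu_X, x$mu_Z,
              if (x$duplicate_xz) ", X[, 1:q] duplicated from Z" else ""))
  invisible(x)
}

#' Generate a synthetic clinical + molecular dataset
#'
#' Draws `y_i` in \{-1, +1\} as a fair Bernoulli coin, then
#' `X[i, j] ~ N(mu_X * 1(y_i = +1), 1)` for informative columns
#' `j <= p_star` and `N(0, 1)` otherwise, and
#' `Z[i, j] ~ N(mu_Z * 1(y_i = +1), 1)` for all q clinical columns, all
#' mutually independent. Under `duplicate_xz` the first q molecular
#' columns are copied from Z after Z is drawn (exact elementwise
#' equality), making the molecular signal fully redundant with the
#' clinical block.
#'
#' @param setting a [sim_setting()] object.
#' @param seed optional RNG seed; output is bit-identical across runs for
#'   a fixed seed.
#' @return An object of class `boost_dataset`: list with `Z` (n x q), `X`
#'   (n x p), `y` (integer -1/+1), `sample_ids`, `feature_ids`,
#'   `covariate_ids` and the setting echo.
#' @export
simulate_dataset <- function(setting, seed = NULL) {
  stopifnot(inherits(setting, "sim_setting"))
  if (!is.null(seed)) set.seed(seed)
  n <- setting$n; p <- setting$p; q <- setting$q
  y <- ifelse(rbinom(n, 1L, 0.5) == 1L, 1L, -1L)
  pos <- y == 1L

  Z <- matrix(rnorm(n * q), n, q)
  if (setting$mu_Z != 0 && q > 0) Z[pos, ] <- Z[pos, ] + setting$mu_Z

  X <- matrix(rnorm(n * p), n, p)
  if (setting$p_star > 0 && setting$mu_X != 0)
    X[pos, seq_len(setting$p_star)] <-
      X[pos, seq_len(setting$p_star)] + setting$mu_X
  if (setting$duplicate_xz) X[, seq_len(q)] <- Z
  if (setting$shuffle) X <- X[, sample.int(p), drop = FALSE]

  structure(list(
    Z = `colnames<-`(Z, paste0("Z", seq_len(q))),
    X = `colnames<-`(X, paste0("X", seq_len(p))),
    y = y,
    sample_ids = sprintf("S%04d", seq_len(n)),
    feature_ids = paste0("X", seq_len(p)),
    covariate_ids = paste0("Z", seq_len(q)),
    setting = setting),
    class = "boost_dataset")
}

#' @export
print.boost_dataset <- function(x, ...) {
  cat(sprintf(
    "Dataset: n = %d samples, q = %d clinical covariates, p = %d ",
    length(x$y), ncol(x$Z), ncol(x$X)))
  cat(sprintf("molecular features (%d positive, %d negative)\n",
              sum(x$y == 1L), sum(x$y == -1L)))
  invisible(x)
}

#' Type-I error / power study over replicated synthetic datasets
#'
#' Generates `n_reps` independent datasets from a [sim_setting()], runs
#' [global_boost_test()] on each, and summarizes the p-value distribution
#' and the rejection rate at level `alpha`. Per-replicate data and test
#' seeds are derived deterministically from the master `seed`, so the
#' study is reproducible and replicate-level seeds are shared when the
#' same master seed is used across settings (paired comparisons across
#' effect sizes).
#'
#' @param setting a [sim_setting()] object.
#' @param n_reps number of replicated datasets.
#' @param alpha rejection level.
#' @param B,mstop,mmax,nu,threads,center,standardize passed to
#'   [global_boost_test()].
#' @param seed master seed.
#' @return An object of class `power_study` with `p_values`,
#'   `rejection_rate`, `p_quantiles`, `alpha` and the setting echo.
#' @export
run_power_study <- function(setting, n_reps = 100, alpha = 0.05, B = 200,
                            mstop = 100, mmax = 1000, nu = 0.1,
                            center = TRUE, standardize = FALSE,
                            seed = 1, threads = 1) {
  stopifnot(inherits(setting, "sim_setting"), n_reps >= 1)
  set.seed(seed)
  data_seeds <- sample.int(.Machine$integer.max, n_reps)
  test_seeds <- sample.int(.Machine$integer.max, n_reps)
  pv <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    d <- simulate_dataset(setting, seed = data_seeds[r])
    tt <- global_boost_test(d$X, d$y, Z = d$Z, B = B, mstop = mstop,
                            mmax = mmax, nu = nu, center = center,
                            standardize = standardize,
                            seed = test_seeds[r], threads = threads)
    pv[r] <- tt$p_value
  }
  structure(list(p_values = pv, rejection_rate = mean(pv <= alpha),
                 p_quantiles = quantile(pv, c(.05, .25, .5, .75, .95)),
                 alpha = alpha, n_reps = n_reps, B = B, mstop = mstop,
                 nu = nu, seed = seed, setting = setting),
            class = "power_study")
}

#' @export
print.power_study <- function(x, ...) {
  print(x$setting)
  cat(sprintf(
    "%d replicates, B = %d, mstop = %s: rejection rate at alpha = %g: %.3f\n",
    x$n_reps, x$B, as.character(x$mstop), x$alpha, x$rejection_rate))
  cat("p-value quantiles:\n")
  print(round(x$p_quantiles, 4))
  invisible(x)
}

#' Study-size profiles
#'
#' Two pre-registered problem sizes for simulation studies: `"desk"`
#' (p = 200, B = 99, 50 replicates — minutes on one core) and `"paper"`
#' (p = 1000, B = 200, 100 replicates — the full benchmark scale, hours).
#'
#' @param name `"desk"` or `"paper"`.
#' @return list with `p`, `B`, `n_reps`.
#' @export
study_profile <- function(name = c("desk", "paper")) {
  switch(match.arg(name),
         desk = list(p = 200L, B = 99L, n_reps = 50L),
         paper = list(p = 1000L, B = 200L, n_reps = 100L))
}
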