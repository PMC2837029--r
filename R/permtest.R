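# permutation p-value, add-one convention: p = (1 + #{ell_b <= ell}) / (B+1)
# (ties counted as <=, conservative; p > 0 always; exactly discrete-uniform
# under exchangeability)
perm_pvalue <- function(ell_observed, ell_perm) {
  (1 + sum(ell_perm <= ell_observed)) / (length(ell_perm) + 1)
}

#' Row-permute a molecular matrix
#'
#' Applies one permutation `sigma` jointly to all p columns, so within-row
#' feature correlation is preserved. Clinical covariates and outcome are,
#' by contract, never permuted.
#'
#' @param X numeric matrix (n x p).
#' @param sigma integer permutation of `1:n`.
#' @return `X[sigma, ]`.
#' @export
permute_molecular <- function(X, sigma) {
  X <- as.matrix(X)
  if (length(sigma) != nrow(X) || !setequal(sigma, seq_len(nrow(X))))
    stop("sigma must be a permutation of 1:n")
  X[sigma, , drop = FALSE]
}

# one step-2 run on an already prepared (and possibly row-permuted) working
# matrix; returns c(ell, mstop_used). Column stats are invariant under row
# permutation, so mu/ssq are reused across permutations.
run_step2 <- function(W, mu, ssq, y1, off, mstop, mmax, nu, eps, aic_mode) {
  if (aic_mode) {
    res <- cwlls_boost(W, mu, ssq, y1, off, as.integer(mmax), nu, eps, TRUE)
    aic <- 2 * length(y1) * drop(res$loss) + 2 * drop(res$df)
    m <- which.min(aic[-1L])
    c(drop(res$loss)[m + 1L], m)
  } else {
    res <- cwlls_boost(W, mu, ssq, y1, off, as.integer(mstop), nu, eps,
                       FALSE)
    c(drop(res$loss)[mstop + 1L], mstop)
  }
}

#' Permutation test of the additional predictive value of a molecular block
#'
#' Tests the global null hypothesis that the molecular variables
#' `X_1, ..., X_p` carry no predictive value for the binary outcome beyond
#' the clinical covariates (equivalently, that all molecular coefficients
#' in the combined model are zero). The procedure: (1) fit the clinical
#' logistic model once and freeze its linear predictor as an offset (or
#' take a supplied risk score / intercept-only offset); (2) run
#' componentwise linear least squares boosting on the molecular block with
#' that offset, with `mstop` fixed or AIC-selected; (3) record the average
#' negative binomial log-likelihood `ell`; (4) repeat step 2 on `B`
#' datasets whose molecular rows are jointly permuted (clinical covariates
#' and outcome untouched, offset reused — it depends only on Z and y);
#' (5) p-value `(1 + #{ell_b <= ell}) / (B + 1)`, with resolution
#' `1/(B + 1)`.
#'
#' In AIC mode the selection is re-run on every permuted dataset so the
#' identical procedure is applied to original and permuted data (required
#' for exchangeability); `aic_once = TRUE` reuses the original selection.
#' All permutations are drawn up front from the master seed, so the result
#' is identical for any `threads` value.
#'
#' @inheritParams boost_fit
#' @param Z clinical covariate matrix or data frame; ignored when
#'   `risk_score` or `offset` is supplied. `NULL` everywhere means
#'   intercept-only adjustment.
#' @param risk_score fixed per-sample clinical risk score replacing the
#'   step-1 fit.
#' @param score_scale `"probability"` or `"linear"` scale of `risk_score`.
#' @param B number of permutations (default 200; the higher, the more
#'   precise the p-value).
#' @param mstop number of boosting iterations, or `"aic"` for AIC
#'   selection (see [select_mstop_aic()]).
#' @param mmax search cap when `mstop = "aic"`.
#' @param seed master RNG seed; drawn at random (and recorded) if `NULL`.
#' @param threads worker count for the permutation loop; the result does
#'   not depend on it.
#' @param aic_once run AIC selection only on the original data and reuse
#'   that `mstop` for permutations.
#' @return An object of class `boost_perm_test`: list with `p_value`,
#'   `ell_observed`, `ell_perm` (length B), `mstop_used` (original +
#'   per-permutation), `B`, `seed`, `resolution`, the offset model and the
#'   configuration echo.
#' @examples
#' d <- simulate_dataset(sim_setting("b", n = 50, p = 60), seed = 3)
#' global_boost_test(d$X, d$y, Z = d$Z, B = 19, mstop = 50, seed = 7)
#' @references The method combines standard logistic regression with the
#'   componentwise linear least squares boosting of Buhlmann and Hothorn's
#'   functional gradient descent framework.
#' @export
global_boost_test <- function(X, y, Z = NULL, risk_score = NULL,
                              score_scale = c("probability", "linear"),
                              offset = NULL, B = 200, mstop = "aic",
                              mmax = 1000, nu = 0.1, center = TRUE,
                              standardize = FALSE, seed = NULL,
                              threads = 1, aic_once = FALSE, eps = 1e-10) {
  out <- as_outcome(y)
  y1 <- as.numeric(out$y == 1L)
  n <- length(y1)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop("X and outcome have different numbers of samples")
  if (!all(is.finite(X))) stop("non-finite values in molecular matrix")
  if (B < 1) stop("B must be >= 1")
  if (n < 2) stop("need at least 2 samples to permute")

  om <- if (!is.null(offset)) resolve_offset(offset, out, n)
        else if (!is.null(risk_score))
          offset_from_risk_score(risk_score, match.arg(score_scale))
        else if (!is.null(Z)) fit_logistic_offset(Z, out)
        else intercept_only_offset(out)
  if (length(om$offset) != n) stop("offset length mismatch")

  aic_mode <- identical(mstop, "aic")
  if (!aic_mode) {
    mstop <- as.integer(mstop)
    if (is.na(mstop) || mstop < 0) stop("mstop must be >= 0 or \"aic\"")
  }
  prep <- prep_design(X, center, standardize)

  obs <- run_step2(prep$W, prep$mu, prep$ssq, y1, om$offset,
                   if (aic_mode) NA_integer_ else mstop, mmax, nu, eps,
                   aic_mode)
  ell_obs <- obs[1L]
  mstop_obs <- as.integer(obs[2L])
  perm_aic <- aic_mode && !aic_once
  mstop_fixed <- if (aic_mode) mstop_obs else mstop

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  perms <- lapply(seq_len(B), function(b) sample.int(n))

  worker <- function(b) {
    run_step2(prep$W[perms[[b]], , drop = FALSE], prep$mu, prep$ssq, y1,
              om$offset, mstop_fixed, mmax, nu, eps, perm_aic)
  }
  res <- if (threads > 1)
    parallel::mclapply(seq_len(B), worker, mc.cores = threads)
  else lapply(seq_len(B), worker)
  res <- do.call(rbind, res)
  ell_perm <- res[, 1L]
  mstop_used <- c(observed = mstop_obs, as.integer(res[, 2L]))

  structure(list(
    p_value = perm_pvalue(ell_obs, ell_perm),
    ell_observed = ell_obs, ell_perm = ell_perm,
    mstop_used = mstop_used, B = as.integer(B), seed = seed,
    resolution = 1 / (B + 1),
    mstop_mode = if (aic_mode) "aic" else "fixed",
    mstop = if (aic_mode) "aic" else mstop, mmax = mmax, nu = nu,
    center = center, standardize = standardize, aic_once = aic_once,
    threads = threads, offset = om, n = n, p = ncol(X),
    method = paste("Permutation test of additional predictive value",
                   "(offset boosting)")),
    class = "boost_perm_test")
}

#' @export
print.boost_perm_test <- function(x, digits = 4, ...) {
  cat("\n\t", x$method, "\n\n")
  cat(sprintf("data: n = %d samples, p = %d molecular features\n",
              x$n, x$p))
  cat(sprintf("offset: %s; mstop: %s%s; nu = %g; B = %d\n",
              x$offset$mode, x$mstop_mode,
              if (x$mstop_mode == "fixed") paste0(" (", x$mstop, ")")
              else sprintf(" (observed mstop = %d)", x$mstop_used[1L]),
              x$nu, x$B))
  cat(sprintf("observed mean neg. log-likelihood: %.*f\n",
              digits, x$ell_observed))
  cat(sprintf("p-value = %.*f (resolution 1/(B+1) = %.*f)\n\n",
              digits, x$p_value, digits, x$resolution))
  invisible(x)
}

#' @export
summary.boost_perm_test <- function(object, ...) {
  q <- quantile(object$ell_perm, c(0, .25, .5, .75, 1))
  structure(list(test = object, perm_quantiles = q),
            class = "summary.boost_perm_test")
}

#' @export
print.summary.boost_perm_test <- function(x, ...) {
  print(x$test)
  cat("Permutation distribution of the mean neg. log-likelihood:\n")
  print(round(x$perm_quantiles, 4))
  invisible(x)
}

#' @export
plot.boost_perm_test <- function(x, ...) {
  graphics::hist(x$ell_perm, breaks = "FD",
                 xlim = range(c(x$ell_perm, x$ell_observed)),
                 main = "Permutation null distribution",
                 xlab = "mean negative log-likelihood", ...)
  graphics::abline(v = x$ell_observed, col = 2, lwd = 2)
  invisible(x)
}

#' Loss-versus-mstop diagnostic
#'
#' Computes the training mean negative log-likelihood as a function of the
#' boosting iteration for the original data and for `B` row-permuted
#' copies of the molecular matrix — the standard diagnostic for judging
#' whether the test result is sensitive to `mstop`: beyond some iteration
#' the original and permuted curves run roughly parallel, and the p-value
#' stabilizes.
#'
#' @inheritParams global_boost_test
#' @param mmax largest iteration on the curve.
#' @return An object of class `boost_diagnostic`: a list with `losses`
#'   (matrix, `B + 1` rows x `mmax + 1` columns; first row = original
#'   data), `m_grid`, `B` and `seed`. Use [pvalue_at()] to read off the
#'   permutation p-value at any `mstop`, `plot()` for the curves, and
#'   `as.data.frame()` for CSV export.
#' @export
boost_diagnostic <- function(X, y, Z = NULL, risk_score = NULL,
                             score_scale = c("probability", "linear"),
                             offset = NULL, mmax = 1000, B = 20, nu = 0.1,
                             center = TRUE, standardize = FALSE,
                             seed = NULL, eps = 1e-10) {
  out <- as_outcome(y)
  y1 <- as.numeric(out$y == 1L)
  n <- length(y1)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  om <- if (!is.null(offset)) resolve_offset(offset, out, n)
        else if (!is.null(risk_score))
          offset_from_risk_score(risk_score, match.arg(score_scale))
        else if (!is.null(Z)) fit_logistic_offset(Z, out)
        else intercept_only_offset(out)
  prep <- prep_design(X, center, standardize)

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  perms <- lapply(seq_len(B), function(b) sample.int(n))

  one <- function(W) drop(cwlls_boost(W, prep$mu, prep$ssq, y1, om$offset,
                                      as.integer(mmax), nu, eps,
                                      FALSE)$loss)
  losses <- matrix(NA_real_, B + 1L, mmax + 1L)
  losses[1L, ] <- one(prep$W)
  for (b in seq_len(B))
    losses[b + 1L, ] <- one(prep$W[perms[[b]], , drop = FALSE])

  structure(list(losses = losses, m_grid = 0:mmax, B = as.integer(B),
                 seed = seed, nu = nu, offset = om),
            class = "boost_diagnostic")
}

#' Permutation p-value at chosen stopping iterations
#'
#' @param diag a [boost_diagnostic()] object.
#' @param mstop integer vector of stopping iterations.
#' @return named numeric vector of p-values, one per `mstop`.
#' @export
pvalue_at <- function(diag, mstop) {
  stopifnot(inherits(diag, "boost_diagnostic"))
  if (any(mstop < 0 | mstop > max(diag$m_grid)))
    stop("mstop outside the diagnostic grid")
  p <- vapply(mstop, function(m) {
    perm_pvalue(diag$losses[1L, m + 1L], diag$losses[-1L, m + 1L])
  }, numeric(1))
  stats::setNames(p, paste0("mstop_", mstop))
}

#' @export
plot.boost_diagnostic <- function(x, ...) {
  graphics::matplot(x$m_grid, t(x$losses[-1L, , drop = FALSE]),
                    type = "l", lty = 1, col = "grey60",
                    xlab = "boosting iteration m",
                    ylab = "mean negative log-likelihood", ...)
  graphics::lines(x$m_grid, x$losses[1L, ], col = 2, lwd = 2)
  invisible(x)
}

#' @export
as.data.frame.boost_diagnostic <- function(x, ...) {
  d <- as.data.frame(t(x$losses))
  names(d) <- c("original", paste0("perm_", seq_len(x$B)))
  cbind(m = x$m_grid, d)
}
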