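#' AIC-based choice of the number of boosting iterations
#'
#' Runs the boosting path once to `mmax` while maintaining the aggregated
#' hat operator `B_m = B_{m-1} + nu * H_{j*_m} (I - B_{m-1})`, where
#' `H_j` is the n x n hat matrix of the univariate fit on `(1, X_j)`
#' (the classical linear-smoother approximation to the binomial boosting
#' path, applied on the gradient scale). The effective degrees of freedom
#' are `df(m) = trace(B_m)`, and
#' `AIC(m) = -2 * loglik(m) + 2 * df(m)` is minimized over `m = 1..mmax`
#' (ties broken by smallest m). `df(0) = 0` and the df path is
#' non-decreasing. The fixed clinical offset contributes no degrees of
#' freedom — it is held fixed, not estimated — so the AIC comparison is
#' internal to the boosting path, which is all that matters for selecting
#' `m`.
#'
#' The operator is an n x n dense matrix, so the search is guarded against
#' very large n; use a fixed `mstop` there instead.
#'
#' @inheritParams boost_fit
#' @param mmax largest iteration number searched (default 1000; apart from
#'   computing time there is little harm in choosing it large).
#' @param n_guard refuse the n x n operator above this sample size.
#' @return An object of class `aic_path`: list with `mstop` (the
#'   minimizer), `m_grid`, `loglik`, `df`, `aic` and the underlying
#'   `boost_fit` run to `mmax`.
#' @examples
#' d <- simulate_dataset(sim_setting("b", n = 50, p = 30), seed = 2)
#' sel <- select_mstop_aic(d$X, d$y, fit_logistic_offset(d$Z, d$y),
#'                         mmax = 100)
#' sel$mstop
#' @export
select_mstop_aic <- function(X, y, offset = NULL, mmax = 1000, nu = 0.1,
                             center = TRUE, standardize = FALSE,
                             eps = 1e-10, n_guard = 5000) {
  if (nrow(as.matrix(X)) > n_guard)
    stop("n exceeds the hat-operator guard (", n_guard,
         "); use a fixed mstop instead")
  if (mmax < 1) stop("mmax must be >= 1")
  fit <- boost_fit(X, y, offset, mstop = mmax, nu = nu, center = center,
                   standardize = standardize, track_df = TRUE, eps = eps)
  ll <- -fit$n * fit$loss_path
  aic <- -2 * ll + 2 * fit$df_path
  m_opt <- which.min(aic[-1L])  # over m = 1..mmax; first min = smallest m
  structure(list(mstop = as.integer(m_opt), m_grid = 0:mmax,
                 loglik = ll, df = fit$df_path, aic = aic, fit = fit),
            class = "aic_path")
}

#' @export
print.aic_path <- function(x, ...) {
  cat(sprintf(
    "AIC path over m = 0..%d: selected mstop = %d (AIC %.3f, df %.2f)\n",
    max(x$m_grid), x$mstop, x$aic[x$mstop + 1L], x$df[x$mstop + 1L]))
  invisible(x)
}

#' @export
plot.aic_path <- function(x, ...) {
  graphics::plot(x$m_grid, x$aic, type = "l", xlab = "boosting iteration m",
                 ylab = "AIC", ...)
  graphics::abline(v = x$mstop, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.aic_path <- function(x, ...) {
  data.frame(m = x$m_grid, loglik = x$loglik, df = x$df, aic = x$aic)
}
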