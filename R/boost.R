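# prepare the working design: optional centering and/or scaling by sd,
# plus the column statistics the kernel needs (means, centered SSQ)
prep_design <- function(X, center = TRUE, standardize = FALSE) {
  n <- nrow(X)
  cm <- colMeans(X)
  centers <- if (center) cm else rep(0, ncol(X))
  scales <- rep(1, ncol(X))
  if (standardize) {
    s <- sqrt(pmax(colSums((X - rep(cm, each = n))^2) / (n - 1), 0))
    scales <- ifelse(s > 0, s, 1)
  }
  W <- sweep(sweep(X, 2, centers, "-"), 2, scales, "/")
  mu <- colMeans(W)
  ssq <- colSums(W^2) - n * mu^2
  ssq[ssq < 0] <- 0
  list(W = W, centers = centers, scales = scales, mu = mu, ssq = ssq)
}

#' Componentwise linear least squares boosting with a fixed offset
#'
#' Step 2 of the two-stage procedure: functional gradient descent on the
#' binomial log-likelihood loss, with componentwise linear least squares as
#' the base procedure, started from the fixed clinical offset. Per
#' iteration the negative gradient `u_i = 1(y_i = +1) - expit(f_i)` is
#' fitted by a univariate regression (with intercept) on every molecular
#' column; the column with the smallest residual sum of squares wins (ties
#' broken by smallest index) and the winning fit, shrunken by `nu`, is
#' added to the current predictor. Slopes accumulate into a sparse
#' coefficient vector, intercept updates into `intercept`, so after
#' `mstop` iterations the combined linear predictor
#' `intercept + X beta + offset` reproduces the iterative fit exactly.
#'
#' With `mstop = 0` the fit is the offset model unchanged, so its average
#' negative log-likelihood equals the step-1 GLM's exactly. Zero-variance
#' columns are retained but can never be selected.
#'
#' @param X numeric molecular matrix (n x p); p may far exceed n.
#' @param y two-level outcome or [encode_outcome()] object.
#' @param offset an [fit_logistic_offset()] / [offset_from_risk_score()] /
#'   [intercept_only_offset()] object, a numeric linear-scale vector, or
#'   `NULL` (intercept-only offset).
#' @param mstop number of boosting iterations (>= 0).
#' @param nu step-length (shrinkage) factor in (0, 1], default 0.1.
#' @param center center the columns of `X` before boosting (default TRUE).
#'   Coefficients are reported on the working scale; `predict()` applies
#'   the same transformation, so fitted probabilities do not depend on
#'   centering.
#' @param standardize also divide columns by their standard deviation
#'   (selection is scale-sensitive; default FALSE).
#' @param track_df maintain the aggregated hat operator and record its
#'   trace (effective degrees of freedom) per iteration; needs an n x n
#'   matrix, used by [select_mstop_aic()].
#' @param eps probability clipping threshold for the loss.
#' @return An object of class `boost_fit` with components `intercept`,
#'   `coefficients` (working scale, mostly zero), `selection_path`,
#'   `loss_path` (length `mstop + 1`, training loss after each iteration,
#'   non-increasing), `df_path` (if tracked), `linear_predictor`,
#'   `fitted.values` (probabilities) and the offset model used.
#' @examples
#' d <- simulate_dataset(sim_setting("b", n = 60, p = 40), seed = 1)
#' om <- fit_logistic_offset(d$Z, d$y)
#' fit <- boost_fit(d$X, d$y, om, mstop = 50)
#' fit
#' @seealso [global_boost_test()], [select_mstop_aic()]
#' @export
boost_fit <- function(X, y, offset = NULL, mstop = 100, nu = 0.1,
                      center = TRUE, standardize = FALSE,
                      track_df = FALSE, eps = 1e-10) {
  out <- as_outcome(y)
  y1 <- as.numeric(out$y == 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y1)
  if (nrow(X) != n) stop("X and outcome have different numbers of samples")
  if (!all(is.finite(X))) stop("non-finite values in molecular matrix")
  if (mstop < 0) stop("mstop must be >= 0")
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]")

  om <- resolve_offset(offset, out, n)
  prep <- prep_design(X, center, standardize)
  res <- cwlls_boost(prep$W, prep$mu, prep$ssq, y1, om$offset,
                     as.integer(mstop), nu, eps, track_df)
  if (isTRUE(res$degenerate))
    warning("degenerate base fit: all molecular columns are constant")

  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("X", seq_len(ncol(X)))
  beta <- drop(res$beta)
  names(beta) <- fn
  f <- drop(res$f)

  structure(list(
    intercept = res$beta0,
    coefficients = beta,
    selection_path = as.integer(res$selection),
    loss_path = drop(res$loss),
    df_path = if (track_df) drop(res$df) else NULL,
    linear_predictor = f,
    fitted.values = prob_from_linear_predictor(f, eps),
    offset = om,
    outcome = out,
    mstop = as.integer(mstop), nu = nu,
    center = center, standardize = standardize,
    centers = prep$centers, scales = prep$scales,
    feature_names = fn, n = n, p = ncol(X), eps = eps),
    class = "boost_fit")
}

#' Componentwise linear least squares base fit
#'
#' One base-procedure step in isolation: for every column `j` of `X`, the
#' ordinary least squares fit of `u` on `(1, X_j)`; the winner is the
#' column with the smallest residual sum of squares, ties broken by
#' smallest index. Zero-variance columns get slope 0 and the total sum of
#' squares as RSS, so they never win unless all columns are constant (then
#' `j_star = 1` with slope 0 and a warning).
#'
#' @param u numeric working response (the negative gradient).
#' @param X numeric matrix (n x p).
#' @return list with `j_star`, `slope`, `intercept` and `rss`.
#' @export
componentwise_base_fit <- function(u, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(u) != n) stop("u and X have different numbers of samples")
  mu <- colMeans(X)
  ssq <- colSums(X^2) - n * mu^2
  ssq[ssq < 0] <- 0
  ubar <- mean(u)
  uc <- u - ubar
  tss <- sum(uc^2)
  sc <- drop(crossprod(X, uc))
  gain <- ifelse(ssq > 0, sc^2 / ssq, 0)
  if (all(ssq == 0)) {
    if (tss > 0) warning("degenerate base fit: all columns are constant")
    return(list(j_star = 1L, slope = 0, intercept = ubar, rss = tss))
  }
  j <- unname(which.max(gain))
  slope <- unname(sc[j] / ssq[j])
  list(j_star = j, slope = slope,
       intercept = unname(ubar - slope * mu[j]),
       rss = unname(tss - gain[j]))
}

#' @export
print.boost_fit <- function(x, digits = 4, ...) {
  cat("Offset boosting fit (componentwise linear least squares)\n")
  cat(sprintf("  n = %d, p = %d, mstop = %d, nu = %g, offset: %s\n",
              x$n, x$p, x$mstop, x$nu, x$offset$mode))
  nz <- sum(x$coefficients != 0)
  cat(sprintf("  nonzero molecular coefficients: %d\n", nz))
  cat(sprintf("  mean neg. log-likelihood: %.*f (offset only) -> %.*f\n",
              digits, x$loss_path[1L], digits,
              x$loss_path[length(x$loss_path)]))
  invisible(x)
}

#' @export
summary.boost_fit <- function(object, ...) {
  nz <- which(object$coefficients != 0)
  sel_tab <- sort(table(object$feature_names[object$selection_path]),
                  decreasing = TRUE)
  structure(list(fit = object, nonzero = nz,
                 coefficients = object$coefficients[nz],
                 selections = sel_tab),
            class = "summary.boost_fit")
}

#' @export
print.summary.boost_fit <- function(x, ...) {
  print(x$fit)
  if (length(x$coefficients)) {
    cat("Selected molecular features (working-scale coefficients):\n")
    print(round(sort(x$coefficients, decreasing = TRUE), 5))
  } else {
    cat("No molecular features selected.\n")
  }
  invisible(x)
}

#' @export
coef.boost_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
fitted.boost_fit <- function(object, ...) object$fitted.values

#' Predict from an offset boosting fit
#'
#' @param object a [boost_fit()] object.
#' @param newdata optional molecular matrix; omitted returns the training
#'   fit. The stored centering/scaling is applied to `newdata`.
#' @param offset fixed offset for the new samples (numeric linear-scale
#'   vector or `offset_model`); defaults to 0 for new data.
#' @param type `"link"` (linear predictor) or `"response"` (probability).
#' @param ... unused.
#' @export
predict.boost_fit <- function(object, newdata = NULL, offset = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear_predictor
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != object$p)
      stop("newdata must have ", object$p, " columns")
    W <- sweep(sweep(newdata, 2, object$centers, "-"), 2,
               object$scales, "/")
    off <- if (is.null(offset)) rep(0, nrow(newdata))
           else if (inherits(offset, "offset_model")) offset$offset
           else as.numeric(offset)
    eta <- object$intercept + drop(W %*% object$coefficients) + off
  }
  if (type == "link") eta
  else prob_from_linear_predictor(eta, object$eps)
}

#' @export
residuals.boost_fit <- function(object,
                                type = c("working", "response", "deviance"),
                                ...) {
  type <- match.arg(type)
  y1 <- as.numeric(object$outcome$y == 1L)
  p <- object$fitted.values
  r <- y1 - p
  switch(type,
         working = r,
         response = r,
         deviance = sign(r) * sqrt(-2 * ifelse(y1 == 1, log(p), log1p(-p))))
}

#' @export
logLik.boost_fit <- function(object, ...) {
  ll <- -object$n * object$loss_path[length(object$loss_path)]
  df <- if (!is.null(object$df_path))
    object$df_path[length(object$df_path)]
  else sum(object$coefficients != 0)
  structure(ll, df = df, nobs = object$n, class = "logLik")
}

#' @export
plot.boost_fit <- function(x, ...) {
  m <- seq_along(x$loss_path) - 1L
  graphics::plot(m, x$loss_path, type = "l",
                 xlab = "boosting iteration m",
                 ylab = "mean negative log-likelihood", ...)
  invisible(x)
}

#' Simulate outcomes from a fitted model
#'
#' Draws -1/+1 outcomes from the fitted per-sample probabilities.
#'
#' @param object a [boost_fit()] object.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data frame with `nsim` columns of -1/+1 outcomes.
#' @export
simulate.boost_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted.values
  as.data.frame(replicate(nsim,
    ifelse(rbinom(length(p), 1L, p) == 1L, 1L, -1L), simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
}
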