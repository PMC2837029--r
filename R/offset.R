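new_offset_model <- function(mode, coefficients, offset, converged = TRUE,
                             n_iter = 0L, dropped = character()) {
  structure(list(mode = mode, coefficients = coefficients,
                 offset = as.numeric(offset), converged = converged,
                 n_iter = n_iter, dropped = dropped),
            class = "offset_model")
}

#' Fit the clinical logistic model and build the fixed offset
#'
#' Step 1 of the two-stage procedure: the clinical covariates are fitted by
#' ordinary maximum-likelihood logistic regression (IRLS) and the fitted
#' linear predictor becomes the per-sample offset that step 2 (boosting on
#' the molecular block) holds fixed. The clinical coefficients are never
#' refitted afterwards.
#'
#' Complete or quasi-complete separation makes "additional predictive
#' value" ill-posed (the clinical model is already degenerate), so it is an
#' error by default; it is flagged when the IRLS fit fails to converge
#' within `maxit` iterations or any coefficient exceeds 15 in absolute
#' value. Constant covariate columns are dropped with a warning.
#'
#' @param Z numeric matrix or data frame of clinical covariates (n x q);
#'   `NULL` or zero columns gives the intercept-only fit. Non-numeric
#'   columns are dummy-encoded (reference = first sorted level).
#' @param y two-level outcome or [encode_outcome()] object.
#' @param tol IRLS convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @param allow_nonconverged downgrade the separation error to a warning.
#' @return An object of class `offset_model` with fields `mode`
#'   (`"fitted_glm"`), `coefficients`, `offset` (the linear predictor),
#'   `converged` and `n_iter`.
#' @examples
#' y <- rep(c(-1, 1), each = 10)
#' Z <- matrix(rnorm(40), 20, 2)
#' fit_logistic_offset(Z, y)
#' @export
fit_logistic_offset <- function(Z, y, tol = 1e-8, maxit = 100,
                                allow_nonconverged = FALSE) {
  out <- as_outcome(y)
  y1 <- as.numeric(out$y == 1L)
  n <- length(y1)
  if (is.null(Z)) {
    Z <- matrix(numeric(0), n, 0)
  } else if (is.data.frame(Z)) {
    Z <- encode_covariates(Z)
  } else {
    Z <- as.matrix(Z)
    storage.mode(Z) <- "double"
  }
  if (nrow(Z) != n) stop("Z and outcome have different numbers of samples")
  if (anyNA(Z)) stop("missing values in clinical covariates")
  if (is.null(colnames(Z)) && ncol(Z) > 0)
    colnames(Z) <- paste0("Z", seq_len(ncol(Z)))

  dropped <- character()
  if (ncol(Z) > 0) {
    const <- apply(Z, 2, function(z) max(z) == min(z))
    if (any(const)) {
      dropped <- colnames(Z)[const]
      warning("dropping constant clinical column(s): ",
              paste(dropped, collapse = ", "))
      Z <- Z[, !const, drop = FALSE]
    }
  }
  q <- ncol(Z)
  if (n <= q + 1) stop("need n > q + 1 samples to fit the clinical model")

  design <- cbind("(Intercept)" = 1, Z)
  fit <- suppressWarnings(
    glm.fit(design, y1, family = binomial(),
            control = glm.control(epsilon = tol, maxit = maxit)))
  beta <- fit$coefficients
  if (!fit$converged || max(abs(beta)) > 15) {
    msg <- paste0("separation detected in the clinical logistic model ",
                  "(non-convergence or |coefficient| > 15); the offset is ",
                  "degenerate")
    if (allow_nonconverged) warning(msg) else stop(msg)
  }
  eta <- drop(design %*% beta)
  new_offset_model("fitted_glm", beta, eta, fit$converged, fit$iter, dropped)
}

#' Build a fixed offset from a published risk score
#'
#' When a per-sample clinical risk score is already available (e.g. from a
#' previous publication) the step-1 fit is skipped: a probability-scale
#' score is logit-transformed, a linear-scale score is used verbatim, and
#' the result enters boosting as the fixed offset. No clinical coefficients
#' are estimated. The score need not come from a logistic model (a
#' classification-tree probability works equally).
#'
#' @param scores numeric per-sample scores.
#' @param scale `"probability"` (scores strictly in (0, 1), logit applied)
#'   or `"linear"` (scores used as-is).
#' @return An `offset_model` with mode `"fixed_risk_score"`.
#' @examples
#' offset_from_risk_score(c(0.5, 0.75), "probability")  # offset 0, log(3)
#' @export
offset_from_risk_score <- function(scores, scale = c("probability", "linear")) {
  scale <- match.arg(scale)
  if (!all(is.finite(scores))) stop("non-finite risk scores")
  if (scale == "probability") {
    bad <- which(scores <= 0 | scores >= 1)
    if (length(bad))
      stop("risk score outside (0,1) at index ", bad[1L])
    eta <- logit(scores)
  } else {
    eta <- as.numeric(scores)
  }
  new_offset_model("fixed_risk_score", numeric(0), eta)
}

#' Intercept-only offset
#'
#' Assess the molecular block without any clinical adjustment: the offset
#' is the constant intercept of the unconditional model,
#' `log(n_plus / n_minus)`.
#'
#' @param y two-level outcome or [encode_outcome()] object.
#' @return An `offset_model` with mode `"intercept_only"` and constant
#'   offset.
#' @examples
#' intercept_only_offset(rep(c(-1, 1), c(15, 97)))  # log(97/15)
#' @export
intercept_only_offset <- function(y) {
  out <- as_outcome(y)
  npos <- sum(out$y == 1L)
  nneg <- sum(out$y == -1L)
  if (npos == 0L || nneg == 0L) stop("degenerate outcome: one class absent")
  b0 <- log(npos / nneg)
  new_offset_model("intercept_only", c("(Intercept)" = b0),
                   rep(b0, length(out$y)))
}

# dummy-encode a clinical data frame (treatment contrasts, reference =
# first sorted level), returning a numeric matrix
encode_covariates <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) || is.logical(df[[j]]))
      df[[j]] <- factor(df[[j]])
  }
  mm <- model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

# accept an offset_model, a numeric vector (linear scale), or NULL
# (intercept-only); used by boost_fit and global_boost_test
resolve_offset <- function(offset, outcome, n) {
  if (is.null(offset)) return(intercept_only_offset(outcome))
  if (inherits(offset, "offset_model")) {
    if (length(offset$offset) != n)
      stop("offset length does not match number of samples")
    return(offset)
  }
  if (is.numeric(offset)) {
    if (length(offset) == 1L) offset <- rep(offset, n)
    if (length(offset) != n)
      stop("offset length does not match number of samples")
    return(offset_from_risk_score(offset, "linear"))
  }
  stop("offset must be an offset_model, a numeric vector, or NULL")
}

#' @export
print.offset_model <- function(x, ...) {
  cat("Fixed clinical offset (mode:", x$mode, ")\n")
  if (length(x$coefficients)) {
    cat("Coefficients (log-odds):\n")
    print(round(x$coefficients, 4))
  }
  cat(sprintf("Offset range: [%.4f, %.4f] over %d samples\n",
              min(x$offset), max(x$offset), length(x$offset)))
  invisible(x)
}
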