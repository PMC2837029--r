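#' Encode a two-level outcome as -1/+1
#'
#' Maps an arbitrary two-level outcome (factor, character, numeric or
#' logical) to the -1/+1 coding used throughout the package. Levels are
#' mapped in sorted order — the lower level becomes -1 — so the coding is
#' invariant to row order. The mapping is recorded for reporting.
#'
#' @param raw vector with exactly two distinct, non-missing values.
#' @return An object of class `boost_outcome`: a list with `y` (integer
#'   vector of -1/+1) and `levels` (the two source labels, named by their
#'   code).
#' @examples
#' encode_outcome(c(0, 1, 1, 0))
#' encode_outcome(c("rem", "rem", "norem"))
#' @export
encode_outcome <- function(raw) {
  if (length(raw) == 0L) stop("empty outcome vector")
  if (anyNA(raw)) stop("outcome contains missing values")
  if (is.factor(raw)) raw <- as.character(raw)
  u <- sort(unique(raw))
  if (length(u) == 1L)
    stop("degenerate outcome: only one class present")
  if (length(u) > 2L)
    stop("outcome has more than two levels: ", paste(u, collapse = ", "))
  y <- ifelse(raw == u[2L], 1L, -1L)
  structure(list(y = as.integer(y),
                 levels = stats::setNames(as.character(u), c("-1", "+1"))),
            class = "boost_outcome")
}

#' @export
print.boost_outcome <- function(x, ...) {
  n <- length(x$y)
  cat(sprintf("Binary outcome: n = %d (%s -> -1 [%d], %s -> +1 [%d])\n",
              n, x$levels[1L], sum(x$y == -1L),
              x$levels[2L], sum(x$y == 1L)))
  invisible(x)
}

# coerce y to boost_outcome; vectors already coded in {-1, +1} pass
# through directly (single-class allowed here — downstream fits that need
# both classes check for themselves)
as_outcome <- function(y) {
  if (inherits(y, "boost_outcome")) return(y)
  if (is.numeric(y) && length(y) && !anyNA(y) && all(y %in% c(-1, 1)))
    return(structure(list(y = as.integer(y),
                          levels = c("-1" = "-1", "+1" = "1")),
                     class = "boost_outcome"))
  encode_outcome(y)
}

#' Probabilities from a linear predictor
#'
#' Inverse-logit transform with clipping: probabilities are forced into
#' `[eps, 1 - eps]` so that log-likelihoods stay finite when a fit
#' saturates.
#'
#' @param eta numeric vector on the logit (log-odds) scale; must be finite.
#' @param eps clipping threshold, default `1e-10`.
#' @return numeric vector of probabilities strictly inside (0, 1).
#' @export
prob_from_linear_predictor <- function(eta, eps = 1e-10) {
  if (!all(is.finite(eta))) stop("non-finite values in linear predictor")
  pmin(pmax(plogis(eta), eps), 1 - eps)
}

#' Logit transform
#' @param p probabilities strictly inside (0, 1).
#' @return log-odds `log(p / (1 - p))`.
#' @export
logit <- function(p) log(p / (1 - p))

#' Average negative binomial log-likelihood
#'
#' The goodness-of-fit statistic of the permutation test:
#' `ell = -(1/n) * sum_i [ 1(y_i = +1) log(pi_i) + 1(y_i = -1) log(1 - pi_i) ]`
#' in nats. A small value indicates good fit; an uninformative model with
#' `pi = 0.5` everywhere gives exactly `log(2)`.
#'
#' @param probs predicted probabilities (clipped to `[eps, 1 - eps]`).
#' @param outcome a [encode_outcome()] object or a two-level vector.
#' @param eps clipping threshold before taking logs.
#' @return scalar mean negative log-likelihood (nonnegative).
#' @examples
#' neg_binomial_loglik(rep(0.5, 4), c(1, -1, 1, -1))  # log(2)
#' @export
neg_binomial_loglik <- function(probs, outcome, eps = 1e-10) {
  out <- as_outcome(outcome)
  if (length(probs) == 0L) stop("empty probability vector")
  if (length(probs) != length(out$y))
    stop("probabilities and outcome have different lengths")
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(ifelse(out$y == 1L, log(p), log1p(-p)))
}

#' Negative gradient of the binomial log-likelihood loss
#'
#' The working response of one boosting iteration on the full logit scale:
#' `u_i = 1(y_i = +1) - expit(f_i)`, each entry in (-1, 1). A saturated
#' observation (large concordant `f_i`) contributes nothing.
#'
#' @param outcome a [encode_outcome()] object or two-level vector.
#' @param f current linear predictor (length n).
#' @return numeric vector `u` of length n.
#' @export
negative_gradient <- function(outcome, f) {
  out <- as_outcome(outcome)
  if (length(f) != length(out$y))
    stop("linear predictor and outcome have different lengths")
  as.numeric(out$y == 1L) - plogis(f)
}
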