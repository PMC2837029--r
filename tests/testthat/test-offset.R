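test_that("intercept-only MLE gives log(n+/n-) as a constant offset", {
  om <- fit_logistic_offset(NULL, rep(c(-1, 1), c(10, 30)))
  expect_equal(unname(om$coefficients), log(3), tolerance = 1e-8)
  expect_true(all(abs(om$offset - log(3)) < 1e-8))

  om2 <- intercept_only_offset(rep(c(-1, 1), c(15, 97)))
  expect_equal(unname(om2$coefficients[1]), log(97 / 15))
  expect_equal(om2$offset, rep(log(97 / 15), 112))
  expect_equal(intercept_only_offset(rep(c(-1, 1), 25))$offset, rep(0, 50))
  expect_error(intercept_only_offset(rep(1, 10)), "degenerate")
})

test_that("saturated 2x2 logistic fit reproduces the log odds-ratio closed form", {
  # cell counts: z=1 rows (a pos, b neg), z=0 rows (c pos, d neg)
  a <- 12; b <- 5; cc <- 7; d <- 16
  z <- rep(c(1, 0), c(a + b, cc + d))
  y <- c(rep(c(1, -1), c(a, b)), rep(c(1, -1), c(cc, d)))
  om <- fit_logistic_offset(matrix(z, ncol = 1), y)
  expect_equal(unname(om$coefficients[2]), log(a * d / (b * cc)),
               tolerance = 1e-7)
  expect_equal(unname(om$coefficients[1]), log(cc / d), tolerance = 1e-7)
})

test_that("clinical GLM coefficients match a direct likelihood-maximization oracle", {
  for (seed in c(3, 17, 91)) {
    set.seed(seed)
    n <- 80; q <- 4
    Z <- matrix(rnorm(n * q), n, q)
    eta <- 0.3 + drop(Z %*% c(0.5, -0.4, 0, 0.2))
    y <- ifelse(runif(n) < plogis(eta), 1, -1)
    om <- fit_logistic_offset(Z, y)
    ref <- oracle_logistic_mle(Z, as.numeric(y == 1))
    expect_equal(unname(om$coefficients), ref, tolerance = 1e-6)
    # offset is exactly the fitted linear predictor
    expect_equal(om$offset,
                 drop(cbind(1, Z) %*% om$coefficients), tolerance = 1e-12)
  }
})

test_that("separation is an error by default and a warning when allowed", {
  y <- rep(c(-1, 1), each = 10)
  Z <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1)  # perfect separator
  expect_error(fit_logistic_offset(Z, y), "separation")
  expect_warning(fit_logistic_offset(Z, y, allow_nonconverged = TRUE),
                 "separation")
})

test_that("constant clinical columns are dropped with a warning", {
  set.seed(1)
  Z <- cbind(rnorm(30), 7)
  y <- rep(c(-1, 1), 15)
  expect_warning(om <- fit_logistic_offset(Z, y), "constant")
  expect_length(om$coefficients, 2)  # intercept + 1 surviving column
})

test_that("risk scores become offsets by logit transform (probability) or verbatim (linear)", {
  expect_equal(offset_from_risk_score(c(0.5, 0.5), "probability")$offset,
               c(0, 0))
  expect_equal(offset_from_risk_score(0.75, "probability")$offset, log(3))
  expect_error(offset_from_risk_score(c(0.5, 1.2), "probability"),
               "outside \\(0,1\\) at index 2")
  lin <- offset_from_risk_score(c(-1.3, 2.2), "linear")
  expect_equal(lin$offset, c(-1.3, 2.2))
  expect_identical(lin$mode, "fixed_risk_score")
  expect_length(lin$coefficients, 0)  # nothing estimated
})

test_that("log-likelihood at the step-1 offset equals the GLM's maximized value", {
  set.seed(5)
  n <- 60
  Z <- matrix(rnorm(n * 3), n, 3)
  y <- ifelse(runif(n) < plogis(0.4 * Z[, 1]), 1, -1)
  om <- fit_logistic_offset(Z, y)
  ell <- neg_binomial_loglik(prob_from_linear_predictor(om$offset), y)
  gfit <- glm(I(y == 1) ~ Z, family = binomial)
  expect_equal(ell, -as.numeric(logLik(gfit)) / n, tolerance = 1e-10)
})
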