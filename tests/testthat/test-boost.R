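# fixed integer toy design used for hand-checkable base fits
toy_design <- function() {
  X <- matrix(c(1, 2, 3, 4, 5, 6,
                2, 1, 2, 1, 2, 1,
                0, 3, 1, 4, 2, 5), 6, 3)
  u <- c(-0.4, 0.3, -0.2, 0.5, -0.1, 0.4)
  list(X = X, u = u)
}

test_that("componentwise base fit matches a brute-force univariate regression loop", {
  td <- toy_design()
  got <- componentwise_base_fit(td$u, td$X)
  ref <- oracle_componentwise(td$u, td$X)
  expect_identical(got$j_star, ref$j_star)
  expect_equal(got$slope, unname(ref$slope), tolerance = 1e-12)
  expect_equal(got$intercept, unname(ref$intercept), tolerance = 1e-12)
  expect_equal(got$rss, ref$rss, tolerance = 1e-12)

  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 10), 20, 10)
    u <- rnorm(20)
    got <- componentwise_base_fit(u, X)
    ref <- oracle_componentwise(u, X)
    expect_identical(got$j_star, ref$j_star)
    expect_equal(got$slope, unname(ref$slope), tolerance = 1e-10)
  }
})

test_that("base fit interpolates p=1 exactly, breaks ties by smallest index, ignores constant columns", {
  r <- componentwise_base_fit(c(-1, 1), matrix(c(-1, 1), 2, 1))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$rss, 0, tolerance = 1e-14)

  set.seed(2)
  x <- rnorm(10); u <- rnorm(10)
  expect_identical(componentwise_base_fit(u, cbind(x, x))$j_star, 1L)

  # a constant column never wins over any varying column
  r2 <- componentwise_base_fit(u, cbind(rep(3, 10), x))
  expect_identical(r2$j_star, 2L)

  expect_warning(r3 <- componentwise_base_fit(u, cbind(rep(1, 10),
                                                       rep(2, 10))),
                 "degenerate")
  expect_identical(r3$j_star, 1L)
  expect_equal(r3$slope, 0)
})

test_that("zero boosting iterations return the offset model unchanged", {
  t <- make_toy(40, 15, seed = 8, signal = 1)
  om <- intercept_only_offset(t$y)
  fit <- boost_fit(t$X, t$y, om, mstop = 0)
  expect_equal(unname(coef(fit)), c(0, rep(0, 15)))
  expect_equal(fit$fitted.values,
               prob_from_linear_predictor(om$offset), tolerance = 1e-14)
  expect_length(fit$loss_path, 1)
})

test_that("one boosting step equals nu times the winning base fit", {
  td <- toy_design()
  y <- c(-1, 1, -1, 1, -1, 1)
  # offset 0: u = y' - 0.5
  u <- as.numeric(y == 1) - 0.5
  ref <- oracle_componentwise(u, td$X)
  fit <- boost_fit(td$X, y, offset = rep(0, 6), mstop = 1, nu = 0.1,
                   center = FALSE)
  expect_identical(fit$selection_path, ref$j_star)
  f1 <- 0.1 * (unname(ref$intercept) + unname(ref$slope) *
                 td$X[, ref$j_star])
  expect_equal(fit$linear_predictor, f1, tolerance = 1e-12)
  expect_lt(fit$loss_path[2], fit$loss_path[1])
})

test_that("a saturated concordant offset leaves nothing to explain", {
  t <- make_toy(30, 8, seed = 4, signal = 1)
  om <- offset_from_risk_score(40 * as.numeric(t$y == 1) - 20, "linear")
  fit <- boost_fit(t$X, t$y, om, mstop = 50)
  expect_true(all(abs(fit$coefficients) < 1e-8))
  expect_true(all(abs(diff(fit$loss_path)) < 1e-8))
})

test_that("training loss is non-increasing along every seeded path", {
  for (seed in 1:5) {
    t <- make_toy(40, 30, seed = seed, signal = if (seed %% 2) 0 else 1)
    fit <- boost_fit(t$X, t$y, mstop = 150, nu = if (seed == 3) 1 else 0.1)
    expect_true(all(diff(fit$loss_path) <= 1e-14))
  }
})

test_that("accumulated coefficients reproduce the iterative linear predictor", {
  t <- make_toy(50, 40, seed = 6, signal = 0.8)
  om <- intercept_only_offset(t$y)
  for (std in c(FALSE, TRUE)) {
    fit <- boost_fit(t$X, t$y, om, mstop = 120, standardize = std)
    # rebuild from the coefficient representation via predict()
    p_rebuilt <- predict(fit, newdata = t$X, offset = om,
                         type = "response")
    expect_equal(p_rebuilt, fit$fitted.values, tolerance = 1e-10)
    expect_lte(sum(fit$coefficients != 0), fit$mstop)
  }
})

test_that("with one predictor and nu = 1 boosting reaches the logistic MLE loss", {
  set.seed(9)
  n <- 40
  x <- rnorm(n)
  y <- ifelse(runif(n) < plogis(1.2 * x - 0.3), 1, -1)
  fit <- boost_fit(matrix(x, ncol = 1), y, offset = rep(0, n),
                   mstop = 2000, nu = 1)
  gfit <- glm(I(y == 1) ~ x, family = binomial)
  expect_equal(fit$loss_path[2001], -as.numeric(logLik(gfit)) / n,
               tolerance = 1e-4)
})

test_that("boosting has no hidden row-order dependence", {
  t <- make_toy(30, 20, seed = 11, signal = 0.7)
  om <- intercept_only_offset(t$y)
  fit <- boost_fit(t$X, t$y, om, mstop = 60)
  set.seed(1); perm <- sample.int(30)
  fitp <- boost_fit(t$X[perm, ], t$y[perm], om$offset[perm], mstop = 60)
  expect_equal(fitp$loss_path, fit$loss_path, tolerance = 1e-12)
  expect_identical(fitp$selection_path, fit$selection_path)
  expect_equal(fitp$fitted.values, fit$fitted.values[perm],
               tolerance = 1e-12)
})

test_that("centering shifts the intercept but not the fitted probabilities", {
  t <- make_toy(30, 10, seed = 13, signal = 1)
  t$X <- t$X + 5   # give the columns nonzero means
  f1 <- boost_fit(t$X, t$y, mstop = 40, center = TRUE)
  f2 <- boost_fit(t$X, t$y, mstop = 40, center = FALSE)
  expect_equal(f1$fitted.values, f2$fitted.values, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1$intercept, f2$intercept)))
  expect_equal(unname(f1$coefficients), unname(f2$coefficients),
               tolerance = 1e-12)
})

test_that("boost_fit validates its inputs", {
  t <- make_toy(10, 3, seed = 1)
  Xbad <- t$X; Xbad[2, 2] <- NA
  expect_error(boost_fit(Xbad, t$y), "non-finite")
  expect_error(boost_fit(t$X, t$y, mstop = -1), "mstop")
  expect_error(boost_fit(t$X, t$y, nu = 0), "nu")
  expect_error(boost_fit(t$X, t$y[-1]), "different numbers")
})
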