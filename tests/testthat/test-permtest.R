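test_that("the add-one p-value convention matches hand-computed examples", {
  # observed 0.62 beats 3 of 4 permuted losses -> p = (1+1)/5
  expect_equal(offsetboost:::perm_pvalue(0.62, c(0.60, 0.70, 0.65, 0.72)),
               0.4)
  expect_equal(offsetboost:::perm_pvalue(1, c(2, 3)), 1 / 3)
  # ties count as <= (conservative)
  expect_equal(offsetboost:::perm_pvalue(0.5, c(0.5, 0.6)), 2 / 3)
})

test_that("molecular permutation moves whole rows jointly", {
  X <- matrix(1:12, 3, 4)
  expect_identical(permute_molecular(X, 1:3), X)
  s <- c(3L, 1L, 2L)
  P <- permute_molecular(X, s)
  for (i in 1:3) expect_identical(P[i, ], X[s[i], ])
  # row multiset preserved under any permutation
  set.seed(1)
  X2 <- matrix(rnorm(50), 10, 5)
  P2 <- permute_molecular(X2, sample.int(10))
  expect_equal(sort(apply(P2, 1, paste, collapse = ",")),
               sort(apply(X2, 1, paste, collapse = ",")))
  expect_error(permute_molecular(X, c(1L, 1L, 2L)), "permutation")
})

test_that("mstop = 0 makes every permuted statistic equal the observed one", {
  t <- make_toy(30, 20, seed = 41, signal = 1)
  res <- global_boost_test(t$X, t$y, B = 10, mstop = 0, seed = 1)
  expect_true(all(res$ell_perm == res$ell_observed))
  expect_equal(res$p_value, 1)
})

test_that("results are reproducible by seed and invariant to the thread count", {
  d <- simulate_dataset(sim_setting("b", n = 40, p = 50), seed = 42)
  r1 <- global_boost_test(d$X, d$y, Z = d$Z, B = 30, mstop = 50, seed = 99,
                          threads = 1)
  r2 <- global_boost_test(d$X, d$y, Z = d$Z, B = 30, mstop = 50, seed = 99,
                          threads = 4)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$ell_perm, r2$ell_perm)

  r3 <- global_boost_test(d$X, d$y, Z = d$Z, B = 30, mstop = 50, seed = 100)
  expect_false(identical(r3$ell_perm, r1$ell_perm))
})

test_that("AIC mode re-selects mstop per permutation unless aic_once is set", {
  d <- simulate_dataset(sim_setting("b", n = 40, p = 30), seed = 43)
  r <- global_boost_test(d$X, d$y, Z = d$Z, B = 5, mstop = "aic",
                         mmax = 60, seed = 3)
  expect_length(r$mstop_used, 6)
  expect_true(all(r$mstop_used >= 1 & r$mstop_used <= 60))

  r1 <- global_boost_test(d$X, d$y, Z = d$Z, B = 5, mstop = "aic",
                          mmax = 60, seed = 3, aic_once = TRUE)
  expect_true(all(r1$mstop_used == r1$mstop_used[1]))
  # fixed mstop at the observed selection reproduces the aic_once run
  r2 <- global_boost_test(d$X, d$y, Z = d$Z, B = 5,
                          mstop = r1$mstop_used[[1]], mmax = 60, seed = 3)
  expect_identical(r2$ell_perm, r1$ell_perm)
})

test_that("offset modes dispatch correctly inside the test", {
  t <- make_toy(30, 10, seed = 44, signal = 0.5)
  rs <- runif(30, 0.2, 0.8)
  r <- global_boost_test(t$X, t$y, risk_score = rs, B = 5, mstop = 10,
                         seed = 1)
  expect_identical(r$offset$mode, "fixed_risk_score")
  expect_equal(r$offset$offset, logit(rs))

  r0 <- global_boost_test(t$X, t$y, B = 5, mstop = 10, seed = 1)
  expect_identical(r0$offset$mode, "intercept_only")
  expect_error(global_boost_test(t$X, t$y, B = 0, mstop = 10), "B must")
})

test_that("the diagnostic loss table yields the same p-value as the test at fixed mstop", {
  d <- simulate_dataset(sim_setting("b", n = 40, p = 40), seed = 45)
  dg <- boost_diagnostic(d$X, d$y, Z = d$Z, mmax = 80, B = 19, seed = 5)
  r <- global_boost_test(d$X, d$y, Z = d$Z, B = 19, mstop = 50, seed = 5)
  expect_equal(unname(pvalue_at(dg, 50)), r$p_value)
  expect_equal(unname(pvalue_at(dg, c(0, 80))[1]), 1)  # mstop 0 -> p = 1
  df <- as.data.frame(dg)
  expect_identical(dim(df), c(81L, 21L))
})
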