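test_that("Weibull embolized fraction has the right anchors and limits", {
  p <- weibull_params(4.768, 3)
  expect_equal(weibull_fraction(0, p), 0)
  # 50% point by construction
  expect_equal(weibull_fraction(4.768 * log(2)^(1 / 3), p), 0.5)
  # direct evaluation oracle
  expect_equal(weibull_fraction(4.2198, p), 1 - exp(-(4.2198 / 4.768)^3))
  expect_equal(weibull_fraction(4.2198, p), 0.5, tolerance = 1e-3)
  expect_equal(weibull_fraction(1e6, p), 1)
  expect_error(weibull_fraction(-1, p), "tension")
  expect_error(weibull_fraction(NaN, p), "tension")
})

test_that("Weibull Px inversion matches root finding and the exponential case", {
  expect_equal(weibull_px(weibull_params(1, 1), 50), log(2), tolerance = 1e-12)
  p <- weibull_params(4.768, 3)
  # independent oracle: root of weibull_fraction - 0.5
  root <- uniroot(function(t) weibull_fraction(t, p) - 0.5, c(0.1, 20),
                  tol = 1e-12)$root
  expect_equal(weibull_px(p, 50), root, tolerance = 1e-8)
  expect_equal(weibull_px(p, 50), 4.2198, tolerance = 1e-4)
  expect_lt(weibull_px(p, 1e-8), 1e-2)  # tension -> 0 as x -> 0
  expect_error(weibull_px(p, 0), "between")
  expect_error(weibull_px(p, 100), "between")
})

test_that("Px composed with the fraction is the identity for random parameters", {
  withr::with_seed(42, {
    for (i in 1:20) {
      p <- weibull_params(runif(1, 0.5, 8), runif(1, 0.5, 6))
      x <- runif(9, 1, 99)
      expect_equal(100 * weibull_fraction(weibull_px(p, x), p), x,
                   tolerance = 1e-8)
    }
  })
})

test_that("curve models are monotone in tension for random parameters", {
  withr::with_seed(7, {
    tension <- sort(runif(50, 0, 10))
    psi <- sort(runif(50, -8, -0.01))
    for (i in 1:20) {
      w <- weibull_params(runif(1, 0.5, 8), runif(1, 0.5, 6))
      expect_true(all(diff(weibull_fraction(tension, w)) >= 0))
      s <- sigmoid_params(runif(1, -5, -0.5), runif(1, 0.5, 6))
      expect_true(all(diff(sigmoid_relcond(psi, s)) >= 0))  # increases with psi
      l <- loglogistic_params(0, runif(1, 100, 500), runif(1, 1, 8),
                              runif(1, 0.5, 3))
      expect_true(all(diff(loglogistic_g(psi, l)) >= 0))
    }
  })
})

test_that("sigmoid relative conductance hits its midpoint and limits", {
  s <- sigmoid_params(-1.35, 3)
  expect_identical(sigmoid_relcond(-1.35, s), 0.5)
  expect_equal(sigmoid_relcond(-0.5, s), 1 / (1 + exp(-2.55)))
  expect_equal(sigmoid_relcond(-0.5, s), 0.9275, tolerance = 1e-4)
  expect_lt(sigmoid_relcond(-60, s), 1e-10)
  expect_error(sigmoid_relcond(Inf, s), "finite")
})

test_that("log-logistic conductance respects bounds, midpoint and degeneracy", {
  l <- loglogistic_params(0, 400, 6, 1.108)
  expect_equal(loglogistic_g(-1.108, l), 200)
  expect_equal(loglogistic_g(-1.810, l), 400 / (1 + (1.810 / 1.108)^6))
  expect_equal(loglogistic_g(-1.810, l), 20.0, tolerance = 0.1)
  expect_error(loglogistic_g(0.5, l), "tension")
  flat <- loglogistic_params(100, 100, 2, 1)
  expect_equal(loglogistic_g(c(-0.5, -2, -5), flat), rep(100, 3))
})

test_that("parameter constructors enforce physical constraints", {
  expect_error(weibull_params(-1, 2), "> 0")
  expect_error(weibull_params(2, 0), "> 0")
  expect_error(sigmoid_params(1.35, 3), "negative")
  expect_error(sigmoid_params(-1.35, -3), "> 0")
  expect_error(loglogistic_params(10, 5, 2, 1), "lower")
  expect_error(loglogistic_params(0, 400, -2, 1), "> 0")
})
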