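test_that("OLS fit recovers a univariate AR(1) coefficient", {
  m <- mvarModel(matrix(0.6, 1, 1))
  x <- simulateMVAR(m, 1e4, seed = 3)
  fit <- fitMVAR(x, order = 1)
  # independent oracle: direct lag-1 regression estimate
  xv <- as.numeric(x)
  aHat <- sum(xv[-1] * xv[-length(xv)]) / sum(xv[-length(xv)]^2)
  expect_lt(abs(mvarCoefficients(fit)[1, 1, 1] - 0.6), 0.02)
  expect_lt(abs(mvarCoefficients(fit)[1, 1, 1] - aHat), 1e-6)
})

test_that("white-noise input yields near-zero coefficients", {
  set.seed(4)
  n <- 2000
  x <- matrix(rnorm(2 * n), 2, n)
  fit <- fitMVAR(x, order = 1)
  expect_true(all(abs(mvarCoefficients(fit)) < 3 / sqrt(n)))
})

test_that("a known 3-node order-2 model is recovered from a long sample", {
  A <- array(0, c(3, 3, 2))
  A[, , 1] <- matrix(c(0.5, 0.3, 0, 0, 0.4, 0.3, 0.2, 0, 0.4), 3, 3)
  A[, , 2] <- diag(c(-0.2, -0.1, -0.15))
  m <- mvarModel(A)
  x <- simulateMVAR(m, 1e5, seed = 11)
  fit <- fitMVAR(x, order = 2)
  expect_lt(max(abs(mvarCoefficients(fit) - A)), 0.05)
})

test_that("fit rejects degenerate inputs", {
  x <- matrix(rnorm(100), 2, 50)
  expect_error(fitMVAR(x, order = 0), "order")
  expect_error(fitMVAR(x, order = 60), "order")
  # duplicated channel makes the regressors rank-deficient
  xd <- rbind(x[1, ], x[1, ])
  expect_error(fitMVAR(xd, order = 2), "rank-deficient")
})

test_that("order selection: BIC consistency, single candidate, AIC >= BIC", {
  m <- mvarModel(matrix(c(0.5, 0.4, 0, 0.5), 2, 2))
  x <- simulateMVAR(m, 5000, seed = 21)
  expect_identical(selectOrder(x, maxOrder = 6, criterion = "bic"), 1L)
  expect_identical(selectOrder(x, maxOrder = 1), 1L)
  set.seed(22)
  for (s in 1:5) {
    xs <- simulateMVAR(m, 300, seed = 100 + s)
    expect_gte(selectOrder(xs, maxOrder = 8, criterion = "aic"),
               selectOrder(xs, maxOrder = 8, criterion = "bic"))
  }
})

test_that("stationary covariance solves the Lyapunov equation", {
  # AR(1), a = 0.5, unit noise: variance = 1 / (1 - 0.25) = 4/3
  m <- mvarModel(matrix(0.5, 1, 1))
  expect_equal(stationaryCovariance(m)[1, 1], 4 / 3, tolerance = 1e-10)
  # 2-node model: analytic Lyapunov vs long-run empirical covariance
  m2 <- mvarModel(matrix(c(0.5, 0.4, 0, 0.5), 2, 2))
  P <- stationaryCovariance(m2)
  x <- simulateMVAR(m2, 1e5, seed = 31)
  expect_lt(max(abs(tcrossprod(x) / ncol(x) - P) / max(abs(P))), 0.1)
})
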