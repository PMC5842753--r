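test_that("PDC of the null model is the identity pattern", {
  m <- mvarModel(array(0, c(3, 3, 1)))
  v <- connValues(pdcSpectrum(m, c(2, 10, 25)))
  for (k in 1:3) {
    expect_equal(diag(v[, , k]), rep(1, 3))
    expect_equal(v[, , k][upper.tri(v[, , k]) | lower.tri(v[, , k])],
                 rep(0, 6))
  }
})

test_that("2-node PDC matches the closed-form expression", {
  m <- mvarModel(matrix(c(0.5, 0.4, 0, 0.5), 2, 2), fs = 250)
  theta <- 2 * pi * 10 / 250
  e <- exp(-1i * theta)
  expected <- Mod(0.4 * e) / sqrt(Mod(1 - 0.5 * e)^2 + Mod(0.4 * e)^2)
  got <- connValues(pdcSpectrum(m, 10))[2, 1, 1]
  expect_lt(abs(got - expected), 1e-10)
})

test_that("sender columns of squared PDC sum to one for random models", {
  set.seed(41)
  for (rep in 1:20) {
    R <- sample(2:5, 1)
    p <- sample(1:3, 1)
    A <- array(rnorm(R * R * p, sd = 0.25), c(R, R, p))
    while (companionRadius(A) >= 0.95) A <- A * 0.9
    v <- connValues(pdcSpectrum(mvarModel(A), 1:30))
    sums <- apply(v^2, c(2, 3), sum)
    expect_lt(max(abs(sums - 1)), 1e-9)
  }
})

test_that("sender-power weighting behaves as documented", {
  m <- mvarModel(matrix(c(0.5, 0.4, 0.2, 0.5), 2, 2))
  epoch <- simulateMVAR(m, 500, seed = 42)
  pdc <- pdcSpectrum(m, 1:30)

  # uniform power -> weights all 1 -> wPDC == PDC
  wU <- weightPDC(pdc, rbind(epoch[1, ], epoch[1, ]))
  expect_equal(connValues(wU), connValues(pdc))

  # doubling one channel's amplitude quadruples its raw power weight
  w1 <- rowMeans(epoch^2)
  epoch2 <- epoch; epoch2[1, ] <- 2 * epoch2[1, ]
  w2 <- rowMeans(epoch2^2)
  expect_equal(unname(w2[1] / w1[1]), 4, tolerance = 1e-12)

  # max normalization (default): weights in (0, 1] with one exactly 1
  w <- connValues(weightPDC(pdc, epoch)) / connValues(pdc)
  wPerSender <- apply(w, 2, max)
  expect_true(all(wPerSender > 0 & wPerSender <= 1 + 1e-12))
  expect_equal(max(wPerSender), 1)
  # mean normalization: weights average to 1
  wm <- connValues(weightPDC(pdc, epoch, normalize = "mean")) / connValues(pdc)
  expect_equal(mean(apply(wm, 2, max)), 1, tolerance = 1e-12)

  expect_error(weightPDC(pdc, rbind(epoch[1, ], 0 * epoch[2, ])), "zero power")
})

test_that("band reduction uses closed-open intervals on the 1 Hz grid", {
  bands <- bandSpec()
  freqs <- 1:30
  expect_identical(pdcnet:::.bandMembers(bands, freqs, 1), 4:7)
  expect_identical(pdcnet:::.bandMembers(bands, freqs, 2), 8:11)
  expect_identical(pdcnet:::.bandMembers(bands, freqs, 3), 12:29)
  expect_error(bandSpec(a = c(4, 8), b = c(6, 12)), "overlap")
  expect_error(bandSpec(a = c(8, 4)), "lower < upper")
})

test_that("subject connectivity averages epochs then bands", {
  tpl <- makeTemplate("CONTROL", roiNames = c("A-L", "A-R"), order = 2,
                      seed = 5)
  s1 <- simulateSubject(tpl, nEpochs = 1, subjectJitterSd = 0, seed = 6)
  ct <- subjectConnectivity(s1, order = 3)
  # one epoch: result equals that epoch's band-averaged wPDC directly
  epoch <- s1@epochs[1, , ]
  fit <- fitMVAR(epoch, order = 3, fs = 250, roiNames = roiNames(s1))
  w <- weightPDC(pdcSpectrum(fit, 1:30), epoch)
  manual <- vapply(1:3, function(k) {
    idx <- pdcnet:::.bandMembers(bandSpec(), 1:30, k)
    apply(connValues(w)[, , idx, drop = FALSE], c(1, 2), mean)
  }, matrix(0, 2, 2))
  expect_equal(connValues(ct), manual, tolerance = 1e-12)

  # frequency-constant connectivity -> identical values in all three bands
  null3 <- mvarModel(array(0, c(3, 3, 1)))
  vals <- connValues(pdcSpectrum(null3, 1:30))
  bt <- pdcnet:::.bandReduce(vals, 1:30, bandSpec())
  expect_equal(bt[, , 1], bt[, , 2])
  expect_equal(bt[, , 2], bt[, , 3])
})

test_that("fitted PDC converges to the analytic PDC of the generator", {
  A <- array(0, c(3, 3, 2))
  A[, , 1] <- matrix(c(0.5, 0.35, 0, 0, 0.4, 0.3, 0.15, 0, 0.45), 3, 3)
  A[, , 2] <- diag(c(-0.2, -0.1, -0.15))
  m <- mvarModel(A)
  x <- simulateMVAR(m, 1e5, seed = 51)
  fit <- fitMVAR(x, order = 2)
  pdcTrue <- connValues(pdcSpectrum(m, 1:30))
  pdcFit <- connValues(pdcSpectrum(fit, 1:30))
  expect_lt(max(abs(pdcTrue - pdcFit)), 0.02)
})
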