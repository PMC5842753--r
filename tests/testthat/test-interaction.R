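test_that("interaction matrix is square, zero-diagonal and reproducible", {
  fx <- fixtureIndependent(n = 30, seed = 201)
  im1 <- interactionMatrix(fx$x, fx$y, forestSpec(200, seed = 12),
                           nRepeats = 4, impRepeats = 5)
  im2 <- interactionMatrix(fx$x, fx$y, forestSpec(200, seed = 12),
                           nRepeats = 4, impRepeats = 5)
  e <- effectsMatrix(im1)
  expect_identical(dim(e), c(2L, 2L))
  expect_identical(diag(e), setNames(c(0, 0), colnames(fx$x)))
  expect_identical(e, effectsMatrix(im2))
  expect_error(interactionMatrix(fx$x[, 1, drop = FALSE], fx$y),
               "at least 2")
})

test_that("an XOR pair shows strongly negative mutual interaction", {
  fx <- fixtureXor(n = 40, nNoise = 0, seed = 202)
  im <- interactionMatrix(fx$x, fx$y, forestSpec(500, seed = 13),
                          nRepeats = 10, impRepeats = 10)
  e <- effectsMatrix(im)
  base <- im@baseline
  expect_lt(e["xorA", "xorB"], -0.5 * base["xorB"])
  expect_lt(e["xorB", "xorA"], -0.5 * base["xorA"])
})

test_that("independent features embedded in a panel do not interact", {
  for (s in c(203, 204, 305)) {
    fx <- fixturePanel(n = 60, seed = s)
    im <- interactionMatrix(fx$x, fx$y, forestSpec(500, seed = 14),
                            nRepeats = 10, impRepeats = 10)
    e <- effectsMatrix(im)
    bound <- 2 * pmax(im@effectSD, max(im@permSD))
    expect_lt(abs(e["indA", "indB"]), bound["indA", "indB"])
    expect_lt(abs(e["indB", "indA"]), bound["indB", "indA"])
  }
})

test_that("removing an unimportant feature leaves others unaffected", {
  fx <- fixturePanel(n = 60, seed = 204)
  set.seed(205)
  x <- cbind(fx$x, junk = rnorm(60))
  im <- interactionMatrix(x, fx$y, forestSpec(500, seed = 15),
                          nRepeats = 10, impRepeats = 10)
  e <- effectsMatrix(im)
  others <- setdiff(colnames(x), "junk")
  bound <- 2 * pmax(im@effectSD["junk", others], max(im@permSD))
  expect_true(all(abs(e["junk", others]) < bound))
})
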