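test_that("Mann-Whitney-Wilcoxon behaves exactly on the worked cases", {
  # x = {1,2} vs y = {3,4}: U = 0, exact two-sided p = 2/6
  expect_equal(mwwTest(c(1, 2, 3, 4), c("a", "a", "b", "b")), 1 / 3,
               tolerance = 1e-12)
  # identical multisets -> maximal p
  expect_equal(mwwTest(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3)), 1)
  # label swap leaves the two-sided p unchanged
  set.seed(91)
  v <- rnorm(20); lab <- rep(c("a", "b"), 10)
  swapped <- ifelse(lab == "a", "b", "a")
  expect_equal(mwwTest(v, lab), mwwTest(v, swapped))
  expect_error(mwwTest(v, rep("a", 20)), "2 classes")
})

test_that("the selection cap is one feature per ten subjects", {
  expect_identical(selectionCap(75), 7L)
  expect_identical(selectionCap(40), 4L)
  expect_identical(selectionCap(9), 1L)
  # cap law holds on arbitrary tables
  set.seed(92)
  for (n in c(20, 34, 50)) {
    fx <- fixtureStrong(n = n, M = 12, k = 3, delta = 1.5, seed = n)
    sel <- selectFeatures(fx$x, fx$y, spec = forestSpec(200, seed = n),
                          nRepeats = 10)
    expect_lte(length(selectedFeatures(sel)), n %/% 10)
  }
})

test_that("screening keeps exactly the significant features, in order", {
  fx <- fixtureStrong(n = 50, M = 30, k = 2, delta = 2, seed = 93)
  rep_ <- permutationImportance(fx$x, fx$y, forestSpec(300, seed = 7),
                                nRepeats = 15)
  keep <- dropInsignificant(rep_)
  expect_identical(keep, rep_@featureNames[rep_@significant])
  expect_true(all(keep %in% colnames(fx$x)))
  expect_true(all(c("f001", "f002") %in% keep))
})

test_that("a duplicated informative feature is not kept twice", {
  fx <- fixtureStrong(n = 50, M = 6, k = 1, delta = 2.5, seed = 94)
  x <- cbind(fx$x, dup = fx$x[, 1])
  sel <- minimalSubset(x, fx$y, cap = 5, spec = forestSpec(500, seed = 8))
  chosen <- selectedFeatures(sel)
  expect_length(intersect(c("f001", "dup"), chosen), 1L)
})

test_that("an XOR pair is selected jointly", {
  fx <- fixtureXor(n = 40, nNoise = 2, seed = 95)
  sel <- minimalSubset(fx$x, fx$y, cap = 4, spec = forestSpec(500, seed = 9))
  expect_true(all(c("xorA", "xorB") %in% selectedFeatures(sel)))
})

test_that("selection results are seeded-reproducible and rank-stable", {
  fx <- fixtureGraded(n = 60, seed = 96)
  r1 <- permutationImportance(fx$x, fx$y, forestSpec(300, seed = 10),
                              nRepeats = 15)
  r2 <- permutationImportance(fx$x, fx$y, forestSpec(300, seed = 10),
                              nRepeats = 15)
  expect_identical(r1@repeats, r2@repeats)
  r3 <- permutationImportance(fx$x, fx$y, forestSpec(300, seed = 11),
                              nRepeats = 15, seed = 123)
  expect_gt(cor(importanceValues(r1), importanceValues(r3),
                method = "spearman"), 0.8)
})
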