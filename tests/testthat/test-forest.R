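test_that("split candidate rule floors log2(M)", {
  expect_identical(splitCandidates(588), 9L)
  expect_identical(splitCandidates(20172), 14L)
  expect_identical(splitCandidates(1), 1L)
})

test_that("every tree's bootstrap holds the minority count from each class", {
  fx <- fixtureStrong(n = 55, M = 10, seed = 81)
  y <- rep(c("TLE", "CONTROL"), c(35, 20))
  fo <- trainBalancedRF(fx$x[1:55, ], y, forestSpec(50, seed = 1))
  perClass <- apply(fo@inbag, 2, function(col) tapply(col, y, sum))
  expect_true(all(perClass == 20))
})

test_that("the C++ traversal kernel reproduces ranger's predictions", {
  fx <- fixtureStrong(n = 48, M = 25, k = 2, delta = 1, seed = 82)
  fo <- trainBalancedRF(fx$x, fx$y, forestSpec(200, seed = 2))
  pa <- predict(fo@fit, as.data.frame(fo@x), predict.all = TRUE,
                num.threads = 1)$predictions
  P <- pdcnet:::.cppForestPredict(fo@flat, fo@x)
  expect_true(all(P == pa))
})

test_that("a separable problem is learned perfectly and unanimously", {
  n <- 30
  x <- matrix(c(rep(1, 15), rep(-1, 15)), n, 1,
              dimnames = list(NULL, "f1"))
  y <- rep(c("CASE", "CTRL"), each = 15)
  fo <- trainBalancedRF(x, y, forestSpec(100, seed = 3),
                        positiveClass = "CASE")
  pr <- predictForest(fo, x)
  expect_identical(as.character(pr$predicted), y)
  expect_true(all(pr$score %in% c(0, 1)))
})

test_that("vote ties resolve toward the positive class", {
  fo <- stumpForest(c(1L, 2L))   # one tree each way -> score 0.5
  pr <- predictForest(fo, matrix(0, 1, 1, dimnames = list("s", "f1")))
  expect_identical(as.character(pr$predicted), "POS")
  expect_equal(pr$score, 0.5)
})

test_that("importance matches an independent per-tree oracle", {
  fx <- fixtureStrong(n = 40, M = 8, k = 1, delta = 2, seed = 83)
  fo <- trainBalancedRF(fx$x, fx$y, forestSpec(100, seed = 4))
  set.seed(99)
  perm <- sample.int(40)
  res <- pdcnet:::.cppPermImportance(fo@flat, fo@x, as.integer(fo@y),
                                     fo@inbag, matrix(perm, ncol = 1), 2L)
  for (j in c(1L, 3L))
    expect_equal(res$importance[j, 1], oracleImportance(fo, j, perm),
                 tolerance = 1e-12)
})

test_that("unused features have importance exactly zero in every repeat", {
  fx <- fixtureStrong(n = 40, M = 5, k = 1, delta = 3, seed = 84)
  x <- cbind(fx$x, constant = 1)   # constant column can never split
  rep_ <- permutationImportance(x, fx$y, forestSpec(100, seed = 5),
                                nRepeats = 10)
  expect_true(all(rep_@repeats["constant", ] == 0))
  expect_false(rep_@significant[match("constant", rep_@featureNames)])
})

test_that("a perfectly separating feature dominates importance", {
  set.seed(85)
  n <- 60
  x <- cbind(sep = rep(c(1, -1), each = n / 2),
             matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, sprintf("n%d", 1:6))))
  y <- rep(c("CASE", "CTRL"), each = n / 2)
  fo <- trainBalancedRF(x, y, forestSpec(300, seed = 6))
  rep_ <- permutationImportance(x, y, forest = fo, nRepeats = 20)
  iv <- importanceValues(rep_)
  expect_identical(names(which.max(iv)), "sep")
  expect_true(rep_@significant[1])
  # independent oracle for the expected drop: permuting a balanced binary
  # separator drives each tree to chance, so the importance should match
  # (mean per-tree OOB accuracy) - 0.5, with the per-tree accuracy taken
  # from ranger's own predictions
  pa <- predict(fo@fit, as.data.frame(fo@x), predict.all = TRUE,
                num.threads = 1)$predictions
  lev <- levels(fo@y)
  treeAcc <- vapply(seq_len(ncol(pa)), function(t) {
    oob <- fo@inbag[, t] == 0
    mean(lev[pa[oob, t]] == y[oob])
  }, numeric(1))
  expect_lt(abs(iv["sep"] - (mean(treeAcc) - 0.5)), 0.1)
})
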