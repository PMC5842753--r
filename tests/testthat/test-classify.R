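test_that("metric panel matches hand-computed 2x2 results", {
  rep_ <- metricPanelFromCounts(TP = 38, FN = 2, FP = 5, TN = 30)
  mt <- metricTable(rep_)
  expect_equal(mt$value[1:5], c(90.7, 95.0, 85.7, 88.4, 93.8))
  expect_identical(unname(confusionCounts(rep_)["TLE", "TLE"]), 38L)

  perfect <- metricPanel(rep(c("A", "B"), 5), rep(c("A", "B"), 5),
                         rep(c(1, 0), 5), "A")
  expect_true(all(metricTable(perfect)$value[1:5] == 100))
  expect_equal(perfect@metrics[["auc"]], 1)

  flat <- metricPanel(rep(c("A", "B"), 5), rep(c("A", "B"), 5),
                      rep(0.5, 10), "A")
  expect_equal(flat@metrics[["auc"]], 0.5)

  expect_error(metricPanel(rep("A", 4), rep("A", 4), 1:4, "A"),
               "one class")
})

test_that("rank-statistic AUC agrees with an independent ROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(301)
  for (i in 1:5) {
    y <- rep(c("pos", "neg"), c(12, 15))
    s <- rnorm(27) + (y == "pos")
    rep_ <- metricPanel(y, ifelse(s > 0.5, "pos", "neg"), s, "pos")
    oracle <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                             levels = c("neg", "pos"),
                                             direction = "<", quiet = TRUE)))
    expect_equal(rep_@metrics[["auc"]], oracle, tolerance = 1e-12)
  }
})

test_that("LOOCV predicts every subject exactly once with a clean fold", {
  fx <- fixtureStrong(n = 20, M = 6, k = 2, delta = 2.5, seed = 301)
  res <- loocv(fx$x, fx$y, spec = forestSpec(150, seed = 16), nRepeats = 8)
  expect_length(res@subjectIds, 20)
  expect_identical(res@subjectIds, rownames(fx$x))
  expect_length(res@report@actual, 20)
  expect_length(res@foldSelections, 20)
  # perfect leak: a feature equal to the class indicator gives 100%
  leak <- cbind(fx$x[, 3:6], label = as.numeric(fx$y == "CASE"))
  res2 <- loocv(leak, fx$y, spec = forestSpec(150, seed = 17), nRepeats = 8)
  expect_equal(unname(res2@report@metrics["accuracy"]), 1)
})

test_that("a feature informative only about the held-out subject is never
           selected in that subject's fold", {
  set.seed(302)
  n <- 20
  y <- rep(c("CASE", "CTRL"), each = n / 2)
  x <- cbind(good1 = ifelse(y == "CASE", 1.5, -1.5) + rnorm(n, sd = 0.5),
             good2 = ifelse(y == "CASE", 1.5, -1.5) + rnorm(n, sd = 0.5),
             leak = rnorm(n, sd = 0.01))
  rownames(x) <- sprintf("S%03d", seq_len(n))
  x["S001", "leak"] <- 50   # huge outlier only for subject 1
  res <- loocv(x, y, spec = forestSpec(200, seed = 18), nRepeats = 10)
  fold1 <- res@foldSelections[["S001"]]
  expect_false("leak" %in% selectedFeatures(fold1))
})

test_that("the sequential system short-circuits on CONTROL diagnoses", {
  rows <- matrix(rnorm(6), 3, 2,
                 dimnames = list(c("s1", "s2", "s3"), c("f1", "f2")))
  calls <- new.env(); calls$n <- 0L
  diagStage <- function(r) c("CONTROL", "TLE", "CONTROL")[seq_len(nrow(r))]
  latStage <- function(r) { calls$n <- calls$n + nrow(r); rep("LTLE", nrow(r)) }
  out <- sequentialSystem(diagStage, latStage, rows)
  expect_identical(unname(out), c("CONTROL", "LTLE", "CONTROL"))
  expect_identical(calls$n, 1L)   # invoked for the single TLE subject only
  # all-control diagnosis never needs a lateralization stage at all
  out2 <- sequentialSystem(function(r) rep("CONTROL", nrow(r)), NULL, rows)
  expect_true(all(out2 == "CONTROL"))
})

test_that("three-class confusion conserves counts and collapses exactly", {
  set.seed(303)
  actual <- sample(c("LTLE", "RTLE", "CONTROL"), 60, replace = TRUE)
  predicted <- sample(c("LTLE", "RTLE", "CONTROL"), 60, replace = TRUE)
  conf <- threeClassConfusion(actual, predicted)
  expect_equal(rowSums(conf)[sort(rownames(conf))],
               table(actual)[sort(rownames(conf))], ignore_attr = TRUE)
  coll <- collapseConfusion(conf)
  a2 <- ifelse(actual == "CONTROL", "CONTROL", "TLE")
  p2 <- ifelse(predicted == "CONTROL", "CONTROL", "TLE")
  expect_equal(coll["TLE", "TLE"], sum(a2 == "TLE" & p2 == "TLE"),
               ignore_attr = TRUE)
  expect_equal(sum(coll), 60)
})
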