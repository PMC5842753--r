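test_that("zero effect size reproduces the control network exactly", {
  tplC <- makeTemplate("CONTROL", seed = 1)
  tplL <- makeTemplate("LTLE", effectSize = 0, seed = 1)
  expect_equal(mvarCoefficients(tplL), mvarCoefficients(tplC))
  expect_true(all(effectSpec(tplL)$delta == 0))
})

test_that("patient templates are mirror images under the L/R pairing", {
  tplL <- makeTemplate("LTLE", effectSize = 0.6, seed = 2)
  tplR <- makeTemplate("RTLE", effectSize = 0.6, seed = 2)
  mirror <- function(nm) ifelse(grepl("-L$", nm), sub("-L$", "-R", nm),
                                sub("-R$", "-L", nm))
  esL <- effectSpec(tplL); esR <- effectSpec(tplR)
  key <- function(df) with(df, order(sender, receiver))
  mirrored <- data.frame(sender = mirror(esL$sender),
                         receiver = mirror(esL$receiver),
                         lag = esL$lag, delta = esL$delta)
  expect_equal(mirrored[key(mirrored), ], esR[key(esR), ],
               ignore_attr = TRUE)
})

test_that("stability is enforced and reported", {
  # 2-ROI, order-1, [[0.5, 0], [0.4, 0.5]]: eigenvalues are 0.5, 0.5
  expect_equal(companionRadius(matrix(c(0.5, 0.4, 0, 0.5), 2, 2)), 0.5)
  # random templates stay stable (property over parameter draws)
  set.seed(61)
  for (i in 1:100) {
    tpl <- makeTemplate(sample(c("CONTROL", "LTLE", "RTLE"), 1),
                        baseCoupling = runif(1, 0.1, 0.4),
                        effectSize = runif(1), oscRho = runif(1, 0.5, 0.9),
                        seed = i)
    expect_lt(companionRadius(tpl), 1)
  }
})

test_that("subject simulation honours the epoch layout and jitter contract", {
  tpl <- makeTemplate("CONTROL", seed = 3)
  s <- simulateSubject(tpl, nEpochs = 60, epochSeconds = 1, fs = 250,
                       seed = 4)
  expect_identical(dim(s@epochs), c(60L, 14L, 250L))
  expect_true(all(is.finite(s@epochs)))
  # determinism under a fixed seed
  s2 <- simulateSubject(tpl, nEpochs = 60, seed = 4)
  expect_identical(s@epochs, s2@epochs)
})

test_that("a diagonal AR(1) template reproduces its stationary variance", {
  tpl <- new("NetworkTemplate",
             coeffs = array(diag(2) * 0.5, c(2, 2, 1)), noiseCov = diag(2),
             fs = 250, roiNames = c("A-L", "A-R"), groupLabel = "CONTROL",
             effectSpec = data.frame(sender = character(),
                                     receiver = character(),
                                     lag = integer(), delta = numeric()),
             baseCoupling = 0)
  s <- simulateSubject(tpl, nEpochs = 1, epochSeconds = 400,
                       subjectJitterSd = 0, seed = 5)
  v <- apply(s@epochs[1, , ], 1, var)
  expect_lt(max(abs(v - 4 / 3)) / (4 / 3), 0.1)
})

test_that("cohort generation delivers requested group sizes and manifests", {
  coh <- simulateCohort(35, 20, 20, nEpochs = 1, seed = 8)
  expect_length(cohortSubjects(coh), 75)
  tab <- table(classLabels(coh))
  expect_equal(as.vector(tab[c("CONTROL", "LTLE", "RTLE")]), c(35, 20, 20))
  expect_false(anyDuplicated(subjectIds(coh)) > 0)

  empty <- simulateCohort(0, 0, 0, seed = 8)
  expect_length(cohortSubjects(empty), 0)
  expect_identical(empty@manifest$nControl, 0L)
})

test_that("a cohort is reproducible from its manifest and its files", {
  coh <- simulateCohort(2, 2, 2, nEpochs = 3, seed = 9,
                        templateParams = list(effectSize = 0.5))
  coh2 <- reproduceCohort(cohortManifest(coh))
  expect_identical(coh@subjects[[1]]@epochs, coh2@subjects[[1]]@epochs)
  expect_identical(coh@subjects[[6]]@epochs, coh2@subjects[[6]]@epochs)

  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  back <- readCohort(dir)
  expect_identical(subjectIds(back), subjectIds(coh))
  expect_identical(classLabels(back), classLabels(coh))
  expect_equal(back@subjects[[3]]@epochs, coh@subjects[[3]]@epochs,
               tolerance = 0)
  # the stored manifest also supports exact re-simulation
  coh3 <- reproduceCohort(cohortManifest(back))
  expect_identical(coh3@subjects[[2]]@epochs, coh@subjects[[2]]@epochs)
})
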