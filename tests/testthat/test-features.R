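test_that("feature counts follow |subset|^2 x nBands", {
  rois82 <- sprintf("R%02d-%s", rep(1:41, each = 2), c("L", "R"))
  t82 <- fakeBandTensor(rois82, seed = 1)
  expect_length(flattenConnectivity(t82), 82^2 * 3)   # 20,172

  rois14 <- defaultRoiNames()
  tMix <- fakeBandTensor(c(rois14, "Extra-L", "Extra-R"), seed = 2)
  expect_length(flattenConnectivity(tMix, rois14), 14^2 * 3)  # 588

  t1 <- fakeBandTensor("Solo-L", bandSpec(theta = c(4, 8)), seed = 3)
  expect_length(flattenConnectivity(t1), 1)

  # property over random subset sizes
  set.seed(71)
  for (i in 1:10) {
    k <- sample(seq_along(rois82), 1)
    sub <- sample(rois82, k)
    expect_length(flattenConnectivity(t82, sub), k^2 * 3)
  }
})

test_that("feature names are deterministic, unique, and band-major", {
  tens <- fakeBandTensor(c("A-L", "A-R"), seed = 4)
  v <- flattenConnectivity(tens)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_identical(names(v)[1:4],
                   c("theta:A-L->A-L", "theta:A-L->A-R",
                     "theta:A-R->A-L", "theta:A-R->A-R"))
  expect_identical(names(v)[5], "alpha:A-L->A-L")
  # value orientation: sender j -> receiver i reads values[i, j, band]
  expect_identical(unname(v["theta:A-L->A-R"]), connValues(tens)[2, 1, 1])
  expect_error(flattenConnectivity(tens, "Nope-L"), "unknown ROI")
})

test_that("feature tables assemble, validate and round-trip", {
  rois <- defaultRoiNames()
  tensors <- lapply(1:5, function(i) fakeBandTensor(rois, seed = i))
  names(tensors) <- sprintf("SUB%02d", 1:5)
  labels <- c("CONTROL", "CONTROL", "LTLE", "RTLE", "LTLE")
  tab <- buildFeatureTable(tensors, labels)
  expect_s4_class(tab, "ConnectivityFeatures")
  expect_identical(dim(featureMatrix(tab)), c(5L, 588L))
  expect_identical(classLabels(tab), labels)

  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(tab, path)
  back <- readFeatureTable(path)
  expect_identical(featureMatrix(back), featureMatrix(tab))
  expect_identical(classLabels(back), classLabels(tab))

  # mismatched band count names both offending subjects
  bad <- c(tensors[1:2],
           list(ODD = fakeBandTensor(rois, bandSpec(theta = c(4, 8)),
                                     seed = 9)))
  expect_error(buildFeatureTable(bad, labels[1:3]), "SUB01.*ODD")
})
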