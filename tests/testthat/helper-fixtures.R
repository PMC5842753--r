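# shared fixtures, all generated in code under fixed seeds

# XOR-labelled pair: individually uninformative, jointly decisive
fixtureXor <- function(n = 40, nNoise = 4, seed = 101) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- ifelse(xor(x1 > 0, x2 > 0), "CASE", "CTRL")
  x <- cbind(xorA = x1, xorB = x2,
             matrix(rnorm(n * nNoise), n,
                    dimnames = list(NULL, sprintf("noise%02d", seq_len(nNoise)))))
  rownames(x) <- sprintf("S%03d", seq_len(n))
  list(x = x, y = y)
}

# k strongly shifted features among noise
fixtureStrong <- function(n = 60, M = 40, k = 1, delta = 2, seed = 7) {
  set.seed(seed)
  y <- rep(c("CASE", "CTRL"), c(ceiling(n / 2), floor(n / 2)))
  x <- matrix(rnorm(n * M), n, M,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(M))))
  for (j in seq_len(k)) x[, j] <- x[, j] + ifelse(y == "CASE", delta, 0)
  list(x = x, y = y)
}

# two independent, additive features: each carries the class signal on a
# disjoint half of the subjects, so neither can substitute for the other
# (removing one does not change how the forest uses the other)
fixtureIndependent <- function(n = 40, seed = 55) {
  set.seed(seed)
  y <- rep(c("CASE", "CTRL"), each = n / 2)
  half <- rep(c(TRUE, FALSE), n / 2)
  x <- cbind(
    indA = ifelse(y == "CASE", 1, -1) * ifelse(half, 1, 0) + rnorm(n, sd = 0.25),
    indB = ifelse(y == "CASE", 1, -1) * ifelse(half, 0, 1) + rnorm(n, sd = 0.25))
  rownames(x) <- sprintf("S%03d", seq_len(n))
  list(x = x, y = y)
}

# the independent pair embedded in a working panel of graded features:
# interaction entries are only interpretable relative to a design the
# forest can still fit after a removal (a 1-2 feature design degenerates)
fixturePanel <- function(n = 60, seed = 203) {
  set.seed(seed)
  y <- rep(c("CASE", "CTRL"), each = n / 2)
  half <- rep(c(TRUE, FALSE), n / 2)
  x <- cbind(
    indA = ifelse(y == "CASE", 1, -1) * ifelse(half, 1, 0) + rnorm(n, sd = 0.25),
    indB = ifelse(y == "CASE", 1, -1) * ifelse(half, 0, 1) + rnorm(n, sd = 0.25),
    g1 = rnorm(n) + ifelse(y == "CASE", 1.5, 0),
    g2 = rnorm(n) + ifelse(y == "CASE", 1.2, 0),
    g3 = rnorm(n) + ifelse(y == "CASE", 0.9, 0),
    g4 = rnorm(n) + ifelse(y == "CASE", 0.7, 0))
  rownames(x) <- sprintf("S%03d", seq_len(n))
  list(x = x, y = y)
}

# graded-effect fixture: most features carry a distinct effect size, so the
# importance ranking is meaningful end to end
fixtureGraded <- function(n = 60, seed = 96) {
  set.seed(seed)
  y <- rep(c("CASE", "CTRL"), each = n / 2)
  deltas <- c(2.5, 2.1, 1.7, 1.3, 1.0, 0.7)
  x <- sapply(1:10, function(j)
    rnorm(n) + if (j <= 6) ifelse(y == "CASE", deltas[j], 0) else 0)
  colnames(x) <- sprintf("f%02d", 1:10)
  rownames(x) <- sprintf("S%03d", seq_len(n))
  list(x = x, y = y)
}

# band-axis tensor with random nonnegative values
fakeBandTensor <- function(rois, bands = bandSpec(), seed = 1) {
  set.seed(seed)
  nb <- length(bandNames(bands))
  R <- length(rois)
  new("ConnectivityTensor",
      values = array(runif(R * R * nb), c(R, R, nb)),
      axisKind = "bands", freqs = numeric(0), bands = bands,
      roiNames = rois)
}

# independent R-side oracle for the permutation importance of feature j:
# mean over trees of the per-tree OOB accuracy drop, computed through
# ranger's own predict() rather than the package's C++ kernel
oracleImportance <- function(forest, j, perm) {
  X <- forest@x
  Xp <- X
  Xp[, j] <- X[perm, j]
  y <- as.character(forest@y)
  p0 <- predict(forest@fit, as.data.frame(X), predict.all = TRUE,
                num.threads = 1)$predictions
  p1 <- predict(forest@fit, as.data.frame(Xp), predict.all = TRUE,
                num.threads = 1)$predictions
  lev <- levels(forest@y)
  drops <- vapply(seq_len(ncol(p0)), function(t) {
    oob <- forest@inbag[, t] == 0
    if (!any(oob)) return(0)
    mean(lev[p0[oob, t]] == y[oob]) - mean(lev[p1[oob, t]] == y[oob])
  }, numeric(1))
  mean(drops)
}

# hand-built forest of single-leaf trees (for vote/tie semantics)
stumpForest <- function(leafLevels, levels = c("POS", "NEG"),
                        positiveClass = "POS") {
  nT <- length(leafLevels)
  flat <- list(nTrees = nT,
               left = replicate(nT, 0L, simplify = FALSE),
               right = replicate(nT, 0L, simplify = FALSE),
               splitVar = replicate(nT, 0L, simplify = FALSE),
               splitVal = replicate(nT, 0, simplify = FALSE),
               predLevel = lapply(leafLevels, as.integer),
               levels = levels, featureNames = "f1")
  x <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "f1"))
  new("BalancedForest", fit = NULL, flat = flat, x = x,
      y = factor(levels, levels = levels),
      inbag = matrix(0L, 2, nT), spec = forestSpec(nT),
      positiveClass = positiveClass)
}
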