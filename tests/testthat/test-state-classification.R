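# Hand-built two-subject fixture: DFCSet + StateModel with known windows.
tinyStateFixture <- function() {
  fi <- data.frame(feature = 1:3, nodeA = c("a", "a", "b"),
                   nodeB = c("b", "c", "c"),
                   name = c("a-b", "a-c", "b-c"))
  feats <- list(
    s1 = matrix(c(1, 2, 9,  0, 0, 0,  5, 5, 5), 3, 3,
                dimnames = list(NULL, fi$name)),
    s2 = matrix(c(4, 4, 4,  1, 1, 1,  2, 2, 2), 3, 3,
                dimnames = list(NULL, fi$name)),
    s3 = matrix(c(6, 6, 6,  3, 3, 3,  0, 1, 2), 3, 3,
                dimnames = list(NULL, fi$name)))
  dfc <- new("DFCSet", features = feats, featureIndex = fi,
             nodeNames = c("a", "b", "c"), stat = "covariance",
             windowTRs = 2L)
  model <- new("StateModel", nStates = 2L, centroids = matrix(0, 2, 3),
               assignments = list(s1 = c(1L, 1L, 1L), s2 = c(1L, 2L, 2L),
                                  s3 = c(2L, 2L, 2L)),
               inertiaCurve = data.frame(), kneeStrength = NA_real_,
               distance = "correlation", totWithin = 0, seed = 1L)
  subjects <- S4Vectors::DataFrame(
    id = c("s1", "s2", "s3"),
    group = factor(c("HC", "SZ", "HC"), levels = c("HC", "SZ")),
    age = c(30, 40, 50), gender = factor(c("M", "F", "M")),
    site = factor(c("s", "s", "s")), panss_positive = c(NA, 10, NA),
    panss_negative = c(NA, 12, NA), panss_total = c(NA, 50, NA))
  mkSig <- function() matrix(rnorm(15), 5, 3,
                             dimnames = list(NULL, c("a", "b", "c")))
  cohort <- new("TimeCourseSet",
                signals = list(s1 = mkSig(), s2 = mkSig(), s3 = mkSig()),
                subjects = subjects, nodeNames = c("a", "b", "c"),
                trSeconds = 2, truth = list())
  list(dfc = dfc, model = model, cohort = cohort)
}

test_that("state datasets follow the assignment bookkeeping", {
  fx <- tinyStateFixture()
  ds <- buildStateDataset(fx$dfc, fx$model, fx$cohort, 1)
  expect_identical(rownames(ds$X), c("s1", "s2"))
  expect_equal(unname(ds$X["s1", "a-b"]), 2)  # median of {1, 2, 9}
  expect_identical(ds$excluded, "s3")
  ds2 <- buildStateDataset(fx$dfc, fx$model, fx$cohort, 2)
  expect_identical(ds2$excluded, "s1")
  # window unit keeps every window with subject labels
  dsw <- buildStateDataset(fx$dfc, fx$model, fx$cohort, 2,
                           sampleUnit = "window")
  expect_identical(nrow(dsw$X), 5L)
  expect_identical(dsw$subject, c(rep("s2", 2), rep("s3", 3)))
  # a state with one class errors informatively
  fx$model@assignments$s2 <- c(1L, 1L, 1L)
  expect_error(buildStateDataset(fx$dfc, fx$model, fx$cohort, 2),
               "one class")
})

test_that("dataset sizes equal a brute-force recount on a real cohort", {
  co <- generateCohort(defaultCohortConfig(nHC = 6, nSZ = 6, targetR = 0,
                                           seed = 41))
  dfc <- computeDFC(co)
  model <- clusterStates(dfc, k = 5, nReplicates = 3, maxIter = 50, seed = 3)
  for (s in 1:5) {
    withWindows <- names(which(vapply(stateSequences(model),
                                      function(a) any(a == s), logical(1))))
    ds <- tryCatch(buildStateDataset(dfc, model, co, s),
                   error = function(e) NULL)
    if (!is.null(ds)) {
      expect_identical(sort(rownames(ds$X)), sort(withWindows))
      expect_identical(sort(ds$excluded),
                       sort(setdiff(names(signals(co)), withWindows)))
    }
  }
})

test_that("the regularization path shrinks fully at the top of the grid", {
  set.seed(6)
  X <- scale(matrix(rnorm(80 * 21), 80, 21))
  y <- factor(rep(c("HC", "SZ"), 40), levels = c("HC", "SZ"))
  path <- enrPath(X, y, alpha = 0.5)
  expect_length(path$lambda, 100)
  expect_equal(range(path$lambda), c(1e-5, 1e5))
  expect_true(all(path$beta[, 1] == 0))          # lambda = 1e5
  expect_false(any(path$retained[, 1]))
  # pure ridge keeps everything nonzero at moderate penalty
  ridge <- enrPath(X, y, alpha = 0)
  mid <- which.min(abs(ridge$lambda - 1e-2))
  expect_true(all(ridge$beta[, mid] != 0))
})

test_that("a planted signal feature dominates retention along the path", {
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 400
    y <- factor(rep(c("HC", "SZ"), each = n / 2), levels = c("HC", "SZ"))
    X <- matrix(rnorm(n * 21), n, 21)
    X[, 7] <- X[, 7] + ifelse(y == "SZ", 1.5, -1.5)
    X <- scale(X)
    colnames(X) <- paste0("C", 1:21)
    path <- enrPath(X, y, alpha = 0.5)
    ret <- rowMeans(path$retained)
    expect_true(all(ret[7] > ret[-7]))
  }
})

test_that("nested CV separates a strong planted contrast", {
  set.seed(50)
  n <- 80
  y <- factor(rep(c("HC", "SZ"), each = n / 2), levels = c("HC", "SZ"))
  X <- matrix(rnorm(n * 21), n, 21, dimnames = list(NULL, paste0("C", 1:21)))
  X[, 3] <- X[, 3] + ifelse(y == "SZ", 2, -2)
  ds <- list(X = X, y = y, subject = paste0("sub", seq_len(n)), stateId = 1,
             sampleUnit = "subject-median", excluded = character(0))
  rep <- nestedCVClassify(ds, seed = 9)
  expect_gte(rep$auc, 0.95)
  expect_true("C3" %in% rep$topGroup$topGroup)
  expect_true(all(rep$importance >= 0 & rep$importance <= 1))
  # the planted feature is flagged with q < 0.05 and the right direction
  gd <- rep$groupDiff
  expect_lt(gd$q[gd$feature == "C3"], 0.05)
  expect_identical(gd$direction[gd$feature == "C3"], -1)  # SZ > HC
})

test_that("subject-grouped folds never split a subject", {
  set.seed(77)
  subject <- rep(sprintf("s%02d", 1:30), each = 4)
  y <- factor(rep(rep(c("HC", "SZ"), each = 15), each = 4))
  fold <- dfcstates:::.groupedStratifiedFolds(y, subject, 5)
  expect_true(all(tapply(fold, subject, function(f) length(unique(f))) == 1))
  # stratification: each fold holds both classes
  expect_true(all(table(fold, y) > 0))
})

test_that("AUC is invariant to monotone transforms of the scores", {
  set.seed(15)
  y <- factor(rep(c("HC", "SZ"), each = 30), levels = c("HC", "SZ"))
  sc <- rnorm(60) + ifelse(y == "SZ", 1, 0)
  a1 <- as.numeric(pROC::auc(pROC::roc(y, sc, levels = c("HC", "SZ"),
                                       direction = "<", quiet = TRUE)))
  a2 <- as.numeric(pROC::auc(pROC::roc(y, plogis(3 * sc + 2),
                                       levels = c("HC", "SZ"),
                                       direction = "<", quiet = TRUE)))
  expect_equal(a1, a2)
})

test_that("top-feature grouping honors degenerate and planted patterns", {
  flat <- matrix(0.5, 6, 4, dimnames = list(NULL, paste0("C", 1:4)))
  expect_warning(g0 <- groupTopFeatures(flat), "identical")
  expect_identical(g0$topGroup, paste0("C", 1:4))
  onehot <- matrix(0, 6, 4, dimnames = list(NULL, paste0("C", 1:4)))
  onehot[, 2] <- 1
  g1 <- groupTopFeatures(onehot)
  expect_identical(g1$topGroup, "C2")
  for (s in 1:5) {
    set.seed(500 + s)
    tier <- c(rep(0.8, 3), rep(0.2, 7))
    ret <- t(replicate(8, tier + rnorm(10, 0, 0.02)))
    colnames(ret) <- paste0("C", 1:10)
    g <- groupTopFeatures(ret)
    expect_identical(sort(g$topGroup), sort(paste0("C", 1:3)))
  }
})

test_that("group difference tests behave at the edges", {
  set.seed(30)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("A", "B", "Cst")))
  X[, 2] <- X[, 2] + rep(c(0, 3), each = 20)
  X[, 3] <- 1
  ds <- list(X = X, y = factor(rep(c("HC", "SZ"), each = 20),
                               levels = c("HC", "SZ")))
  out <- groupDifferenceTest(ds, c("A", "B", "Cst"))
  expect_lt(out$q[out$feature == "B"], 0.01)
  expect_identical(out$direction[out$feature == "B"], -1)
  expect_identical(out$p[out$feature == "Cst"], 1)
  expect_true(out$degenerate[out$feature == "Cst"])
  single <- groupDifferenceTest(ds, "B")
  expect_identical(single$p, single$q)
  expect_true(all(out$q >= out$p))
})
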