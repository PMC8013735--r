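test_that("single-state identity covariance reproduces itself in the signal", {
  cfg <- cohortConfig(
    nHC = 1, nSZ = 1, nNodes = 4, nStates = 1, nTimepoints = 10000,
    stateCovariances = list(hc = list(diag(4)), sz = list(diag(4))),
    transitionMatrices = list(hc = matrix(1, 1, 1), sz = matrix(1, 1, 1)),
    symptomLink = list(from = 1, to = 1, targetR = 0, noiseSd = 10),
    seed = 5)
  co <- generateCohort(cfg)
  S <- cov(signals(co)[[1]])
  expect_lt(max(abs(S - diag(4))), 0.05)
})

test_that("generation is bit-identical under equal seeds and differs across seeds", {
  cfg <- defaultCohortConfig(nHC = 3, nSZ = 3, targetR = 0, seed = 9)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(signals(a), signals(b))
  expect_identical(as.data.frame(subjectInfo(a)), as.data.frame(subjectInfo(b)))
  cfg2 <- defaultCohortConfig(nHC = 3, nSZ = 3, targetR = 0, seed = 10)
  expect_false(identical(signals(a), signals(generateCohort(cfg2))))
})

test_that("empirical transition frequencies converge to the configured chain", {
  P <- defaultCohortConfig()@transitionMatrices$hc
  set.seed(31)
  s <- dfcstates:::.sampleChain(P, 1e5)
  est <- transitionMatrix(s, nrow(P))$matrix
  expect_lte(max(abs(est - P)), 0.02)
})

test_that("a null configuration plants no group contrast", {
  co <- generateCohort(defaultCohortConfig(nHC = 12, nSZ = 12,
                                           nullEffects = TRUE, seed = 21))
  dfc <- computeDFC(co)
  grp <- as.character(subjectInfo(co)$group)
  subjMeans <- t(sapply(dfc@features, colMeans))
  diff <- colMeans(subjMeans[grp == "SZ", ]) - colMeans(subjMeans[grp == "HC", ])
  # per-cell Monte-Carlo error from the between-subject spread
  se <- sqrt(apply(subjMeans[grp == "SZ", ], 2, var) / 12 +
             apply(subjMeans[grp == "HC", ], 2, var) / 12)
  expect_true(all(abs(diff) < 4 * se + 0.02))
})

test_that("planted symptom link hits its target correlation at scale", {
  co <- generateCohort(defaultCohortConfig(nHC = 2, nSZ = 500, seed = 33))
  info <- as.data.frame(subjectInfo(co))
  phat <- co@truth$linkPhat
  score <- info$panss_total[match(names(phat), info$id)]
  keep <- is.finite(phat) & is.finite(score)
  expect_gt(sum(keep), 200)
  r <- cor(phat[keep], score[keep])
  expect_lt(abs(r - 0.40), 0.05)
})

test_that("degenerate configurations are rejected with informative errors", {
  bad <- defaultCohortConfig()
  covs <- bad@stateCovariances
  covs$hc[[3]] <- covs$hc[[3]] - diag(5, 7)   # strongly negative definite
  expect_error(
    cohortConfig(nHC = 2, nSZ = 2, nNodes = 7, nStates = 5,
                 stateCovariances = covs,
                 transitionMatrices = bad@transitionMatrices,
                 symptomLink = bad@symptomLink,
                 nodeNames = bad@nodeNames, nodeGroups = bad@nodeGroups),
    "state 3")
  expect_error(defaultCohortConfig(targetR = 1.2), "targetR")
  # infeasible link: no spread in the empirical transition probability
  cfg <- cohortConfig(
    nHC = 1, nSZ = 3, nNodes = 2, nStates = 2, nTimepoints = 50,
    stateCovariances = list(hc = list(diag(2), diag(2)),
                            sz = list(diag(2), diag(2))),
    transitionMatrices = list(hc = diag(2), sz = diag(2)),  # absorbing
    symptomLink = list(from = 1, to = 2, targetR = 0.4, noiseSd = 10),
    seed = 2)
  expect_error(generateCohort(cfg), "infeasible")
})

test_that("default preset matches the study design it emulates", {
  cfg <- defaultCohortConfig()
  expect_identical(cfg@nTimepoints, 144L)
  expect_identical(cfg@nNodes, 7L)
  expect_identical(cfg@nStates, 5L)
  for (P in cfg@transitionMatrices)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  # well-separated states: vectorized centroid correlations below 0.3
  cent <- t(sapply(cfg@stateCovariances$hc, vectorizeFC))
  cc <- cor(t(cent))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.3)
  # planted contrasts point the documented way
  sz <- cfg@stateCovariances$sz; hc <- cfg@stateCovariances$hc
  pcu <- match(cfg@nodeGroups$PCu, cfg@nodeNames)
  pcc <- match(cfg@nodeGroups$PCC, cfg@nodeNames)
  acc <- match(cfg@nodeGroups$ACC, cfg@nodeNames)
  expect_true(all(sz[[1]][pcu, pcc] > hc[[1]][pcu, pcc]))
  expect_true(all(sz[[4]][pcu, pcc] > hc[[4]][pcu, pcc]))
  expect_lt(sz[[2]][acc[1], acc[2]], hc[[2]][acc[1], acc[2]])
  # SZ 2->4 transition probability elevated relative to HC
  expect_gt(cfg@transitionMatrices$sz[2, 4], cfg@transitionMatrices$hc[2, 4])
})

test_that("windowed covariance within a long single-state run converges", {
  cfg <- cohortConfig(
    nHC = 1, nSZ = 1, nNodes = 3, nStates = 1, nTimepoints = 5000,
    stateCovariances = list(
      hc = list(matrix(c(1, .5, .2, .5, 1, -.3, .2, -.3, 1), 3)),
      sz = list(matrix(c(1, .5, .2, .5, 1, -.3, .2, -.3, 1), 3))),
    transitionMatrices = list(hc = matrix(1, 1, 1), sz = matrix(1, 1, 1)),
    symptomLink = list(from = 1, to = 1, targetR = 0, noiseSd = 10),
    seed = 8)
  co <- generateCohort(cfg)
  x <- signals(co)[[1]]
  taper <- buildTaper(20, 3, 2)
  res <- slidingDFC(x, taper)
  # signal is z-scored inside slidingDFC, so compare to the correlation matrix
  target <- cov2cor(cfg@stateCovariances$hc[[1]])
  est <- colMeans(res$features)
  tgt <- vectorizeFC(target)
  # MC error of a mean over heavily overlapping windows ~ sqrt(L/N)
  expect_lt(max(abs(est - tgt)), 3 * sqrt(21 / 5000))
})
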