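test_that("partial correlation reduces to Pearson without covariates", {
  set.seed(1)
  x <- rnorm(40); y <- rnorm(40)
  pc <- partialCorrelation(x, y)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-10)
})

test_that("partial correlation matches the normal-equations oracle", {
  set.seed(2)
  for (i in 1:10) {
    n <- 50L
    Z <- cbind(rnorm(n), rnorm(n))
    x <- rnorm(n) + 0.5 * Z[, 1]
    y <- rnorm(n) - 0.3 * Z[, 2]
    pc <- partialCorrelation(x, y, Z)
    expect_equal(pc$r, oraclePartialCor(x, y, Z), tolerance = 1e-10)
    expect_identical(pc$df, n - 4L)
  }
})

test_that("perfect confounds degenerate gracefully", {
  set.seed(3)
  z <- rnorm(30)
  y <- 2 * z + 1           # exact function of the covariate
  x <- rnorm(30)
  pc <- partialCorrelation(x, y, cbind(z))
  expect_true(pc$degenerate)
  expect_true(is.na(pc$r))
})

test_that("partial correlation is invariant to affine transforms", {
  set.seed(4)
  n <- 60
  Z <- cbind(rnorm(n))
  x <- rnorm(n); y <- x + rnorm(n) + Z[, 1]
  r0 <- partialCorrelation(x, y, Z)$r
  r1 <- partialCorrelation(3 * x - 7, -2 * y + 1, cbind(5 * Z + 2))$r
  expect_equal(abs(r1), abs(r0), tolerance = 1e-10)
  expect_equal(r1, -r0, tolerance = 1e-10)  # sign flips with y scaling < 0
})

test_that("insufficient observations are rejected with the minimum", {
  expect_error(partialCorrelation(rnorm(4), rnorm(4), cbind(rnorm(4), rnorm(4))),
               "k \\+ 2")
})

test_that("BH adjustment matches the step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_equal(bhFDR(p), rep(0.05, 5))
  expect_equal(bhFDR(p), oracleBH(p))
  expect_equal(bhFDR(0.037), 0.037)
  expect_equal(bhFDR(rep(0.2, 4)), rep(0.2, 4))
  set.seed(5)
  pr <- runif(30)
  q <- bhFDR(pr)
  expect_equal(q, oracleBH(pr), tolerance = 1e-12)
  o <- order(pr)
  expect_true(all(diff(q[o]) >= -1e-12))   # monotone after sorting
  expect_true(all(q >= pr))
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("associations reduce to plain Pearson without usable covariates", {
  co <- generateCohort(defaultCohortConfig(nHC = 2, nSZ = 60,
                                           missingFraction = 0, seed = 55))
  K <- 5
  seqs <- co@truth$stateSequences
  fm <- t(sapply(seqs, function(sq) {
    tm <- transitionMatrix(sq, K)
    v <- flattenTransitions(tm$matrix)
    v[rep(tm$unvisited, each = K)] <- NA
    v
  }))
  rownames(fm) <- names(seqs)
  rep0 <- associateTransitions(fm, co, scales = "panss_total",
                               covariates = character(0))
  info <- as.data.frame(subjectInfo(co))
  sz <- info[info$group == "SZ", ]
  f <- "P(2->4)"
  x <- fm[match(sz$id, rownames(fm)), f]
  keep <- is.finite(x) & is.finite(sz$panss_total)
  expect_equal(rep0$r[rep0$feature == f], cor(x[keep], sz$panss_total[keep]),
               tolerance = 1e-12)
  # q never smaller than p, within each scale family
  expect_true(all(rep0$q >= rep0$p - 1e-15, na.rm = TRUE))
})

test_that("covariate adjustment removes a planted site confound", {
  co <- generateCohort(defaultCohortConfig(nHC = 2, nSZ = 150, targetR = 0,
                                           missingFraction = 0, nSites = 3,
                                           siteEffect = 12, seed = 66))
  info <- as.data.frame(subjectInfo(co))
  sz <- info[info$group == "SZ", ]
  site_num <- as.integer(sz$site) - 1L
  set.seed(1)
  x <- site_num + rnorm(nrow(sz), 0, 0.5)   # a site-loaded measurement
  raw <- cor(x, sz$panss_total)
  expect_gt(abs(raw), 0.25)   # the confound is real
  adj <- partialCorrelation(x, sz$panss_total,
                            dfcstates:::.covariateDesign(sz[, "site",
                                                            drop = FALSE]))
  expect_false(adj$degenerate)
  expect_lt(abs(adj$r), abs(raw) / 2, label = "adjusted site association")
  expect_lt(abs(adj$r), 0.15, label = "site effect removed by adjustment")
})

test_that("scales with no scores are skipped with a warning", {
  co <- generateCohort(defaultCohortConfig(nHC = 2, nSZ = 30, targetR = 0,
                                           seed = 12))
  fm <- matrix(runif(30), 30, 1,
               dimnames = list(as.data.frame(subjectInfo(co))$id[3:32],
                               "P(1->1)"))
  info <- as.data.frame(subjectInfo(co))
  co@subjects$panss_positive <- NA_real_
  expect_warning(
    rep <- associateTransitions(fm, co,
                                scales = c("panss_positive", "panss_total"),
                                covariates = character(0)),
    "panss_positive")
  expect_true(all(rep$scale == "panss_total"))
})
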