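#' Default regularization grid
#'
#' 100 logarithmically spaced penalty strengths between 1e-5 and 1e5.
#' @return decreasing numeric vector of length 100.
#' @export
defaultLambdaGrid <- function() sort(10^seq(-5, 5, length.out = 100), decreasing = TRUE)

#' Assemble the per-state classification dataset
#'
#' Collects, for one connectivity state, the windowed features of every
#' subject's windows assigned to that state, as samples for SZ-vs-HC
#' classification. The default sampling unit is the subject: one row per
#' subject, the elementwise median of its windows in the state (avoiding
#' within-subject leakage across CV folds); subjects with no windows in the
#' state are excluded and listed. With `sampleUnit = "window"` every window is
#' a sample and fold construction downstream is grouped by subject.
#'
#' @param dfc a [DFCSet-class].
#' @param model a [StateModel-class] fitted on `dfc`.
#' @param cohort the [TimeCourseSet-class] providing group labels.
#' @param stateId the state (1..K).
#' @param sampleUnit `"subject-median"` (default) or `"window"`.
#' @return list with `X` (samples x P), `y` (factor HC/SZ), `subject`
#'   (id per sample), `excluded` (ids with no windows in the state),
#'   `stateId`, `sampleUnit`.
#' @export
buildStateDataset <- function(dfc, model, cohort, stateId,
                              sampleUnit = c("subject-median", "window")) {
  sampleUnit <- match.arg(sampleUnit)
  stopifnot(is(dfc, "DFCSet"), is(model, "StateModel"), is(cohort, "TimeCourseSet"))
  ids <- names(dfc@features)
  if (!setequal(ids, names(model@assignments)))
    stop("dfc and state model cover different subjects")
  info <- subjectInfo(cohort)
  grp <- stats::setNames(as.character(info$group), as.character(info$id))
  rows <- list(); ys <- character(); subj <- character(); excluded <- character()
  for (id in ids) {
    sel <- model@assignments[[id]] == stateId
    if (!any(sel)) { excluded <- c(excluded, id); next }
    W <- dfc@features[[id]][sel, , drop = FALSE]
    if (sampleUnit == "subject-median") {
      rows[[length(rows) + 1L]] <- apply(W, 2, stats::median)
      ys <- c(ys, grp[[id]]); subj <- c(subj, id)
    } else {
      rows[[length(rows) + 1L]] <- W
      ys <- c(ys, rep(grp[[id]], nrow(W))); subj <- c(subj, rep(id, nrow(W)))
    }
  }
  X <- do.call(rbind, rows)
  if (sampleUnit == "subject-median") rownames(X) <- subj
  y <- factor(ys, levels = c("HC", "SZ"))
  if (nlevels(droplevels(y)) < 2L)
    stop("state ", stateId, ": only one class remains after exclusions")
  list(X = X, y = y, subject = subj, excluded = excluded,
       stateId = stateId, sampleUnit = sampleUnit)
}

#' Elastic-net logistic regularization path
#'
#' Fits the penalized logistic model at every grid value of the
#' regularization strength (intercept unpenalized), mixing L1 and L2 norms
#' via `alpha` (1 = lasso, 0 = ridge). A feature is *retained* at a grid
#' point when its coefficient is strictly nonzero there.
#'
#' @param X samples x features matrix (standardize before calling: the fit
#'   uses the features as given).
#' @param y two-level factor (second level is the modelled class).
#' @param alpha elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param lambdaGrid penalty grid (default [defaultLambdaGrid()]).
#' @return list with `lambda` (decreasing), `a0` (intercepts), `beta`
#'   (features x lambda coefficient matrix) and `retained` (logical
#'   features x lambda).
#' @export
enrPath <- function(X, y, alpha = 0.5, lambdaGrid = defaultLambdaGrid()) {
  stopifnot(is.matrix(X), nlevels(factor(y)) == 2L)
  lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                        lambda = lambdaGrid, standardize = FALSE,
                        maxit = 1e5)
  beta <- as.matrix(fit$beta)
  # glmnet may stop early on degenerate paths; pad with the last solution
  if (ncol(beta) < length(lambdaGrid)) {
    pad <- length(lambdaGrid) - ncol(beta)
    beta <- cbind(beta, beta[, rep(ncol(beta), pad), drop = FALSE])
    a0 <- c(fit$a0, rep(fit$a0[length(fit$a0)], pad))
  } else a0 <- fit$a0
  colnames(beta) <- NULL
  list(lambda = lambdaGrid, a0 = unname(a0), beta = beta,
       retained = beta != 0)
}

# Stratified fold labels; grouped by subject so no subject is split.
.groupedStratifiedFolds <- function(y, subject, nFolds) {
  su <- !duplicated(subject)
  ids <- subject[su]; yu <- y[su]
  fold_of <- stats::setNames(integer(length(ids)), ids)
  for (cls in levels(yu)) {
    members <- sample(ids[yu == cls])
    if (length(members) < nFolds)
      stop("class ", cls, " has only ", length(members),
           " subjects; at least ", nFolds, " are required for ", nFolds,
           "-fold stratified CV")
    fold_of[members] <- rep_len(seq_len(nFolds), length(members))
  }
  unname(fold_of[subject])
}

.zfit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
.zapply <- function(X, z) sweep(sweep(X, 2, z$mu), 2, z$sd, "/")

#' Nested cross-validated elastic-net classification
#'
#' Quantifies SZ-vs-HC separability of one state's connectivity features by
#' 10-fold nested cross-validation with a 9:1 train-test ratio in both loops:
#' the inner loop (9-fold on the outer-training set) selects the penalty
#' strength minimizing inner-CV misclassification error over the 100-point
#' grid; the outer test predictions are pooled into a single ROC/AUC.
#' Feature importance is the *retention proportion*: the fraction of inner
#' models (inner folds x grid points) in which a feature's coefficient stayed
#' nonzero, averaged over outer folds. Features are z-scored with
#' training-split statistics only. The report also carries the ANOVA/Tukey
#' top feature group ([groupTopFeatures()]) and per-feature Welch/BH group
#' differences over the selected group ([groupDifferenceTest()]).
#' Deterministic given `seed`.
#'
#' @param ds dataset from [buildStateDataset()].
#' @param outerFolds outer folds (default 10).
#' @param innerFolds inner folds (default 9, giving 9:1 in both loops).
#' @param alpha elastic-net mixing (default 0.5).
#' @param lambdaGrid penalty grid (default [defaultLambdaGrid()]).
#' @param seed integer seed.
#' @return list (classification report): `stateId`, `auc`, `roc`
#'   (data.frame), `importance` (per-feature retention proportion),
#'   `retentionPerFold` (outer folds x features), `topGroup`, `groupDiff`,
#'   `lambdaChosen`, `predictions`.
#' @export
nestedCVClassify <- function(ds, outerFolds = 10L, innerFolds = 9L,
                             alpha = 0.5, lambdaGrid = defaultLambdaGrid(),
                             seed = 1L) {
  X <- ds$X; y <- ds$y; subject <- ds$subject
  P <- ncol(X)
  set.seed(seed)
  fold <- .groupedStratifiedFolds(y, subject, outerFolds)
  lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)
  nL <- length(lambdaGrid)
  retention <- matrix(NA_real_, outerFolds, P,
                      dimnames = list(NULL, colnames(X)))
  scores <- rep(NA_real_, length(y))
  lambdaChosen <- numeric(outerFolds)
  for (f in seq_len(outerFolds)) {
    tr <- fold != f; te <- !tr
    ifold <- .groupedStratifiedFolds(y[tr], subject[tr], innerFolds)
    err <- matrix(0, innerFolds, nL)
    ret_acc <- matrix(0, P, nL)
    for (g in seq_len(innerFolds)) {
      itr <- which(tr)[ifold != g]; ite <- which(tr)[ifold == g]
      z <- .zfit(X[itr, , drop = FALSE])
      path <- enrPath(.zapply(X[itr, , drop = FALSE], z), y[itr],
                      alpha = alpha, lambdaGrid = lambdaGrid)
      eta <- cbind(1, .zapply(X[ite, , drop = FALSE], z)) %*%
        rbind(path$a0, path$beta)
      pred <- eta > 0
      err[g, ] <- colMeans(pred != (y[ite] == levels(y)[2]))
      ret_acc <- ret_acc + path$retained
    }
    # ties -> largest lambda (sparsest model)
    lamIdx <- which.min(colMeans(err))
    lambdaChosen[f] <- lambdaGrid[lamIdx]
    retention[f, ] <- rowMeans(ret_acc) / innerFolds
    z <- .zfit(X[tr, , drop = FALSE])
    path <- enrPath(.zapply(X[tr, , drop = FALSE], z), y[tr],
                    alpha = alpha, lambdaGrid = lambdaGrid)
    eta <- cbind(1, .zapply(X[te, , drop = FALSE], z)) %*%
      c(path$a0[lamIdx], path$beta[, lamIdx])
    scores[te] <- stats::plogis(eta)
  }
  roc <- pROC::roc(response = y, predictor = scores, levels = c("HC", "SZ"),
                   direction = "<", quiet = TRUE)
  importance <- colMeans(retention)
  topGroup <- groupTopFeatures(retention)
  groupDiff <- groupDifferenceTest(ds, topGroup$topGroup)
  list(stateId = ds$stateId, auc = as.numeric(pROC::auc(roc)),
       roc = data.frame(fpr = 1 - roc$specificities, tpr = roc$sensitivities),
       importance = importance, retentionPerFold = retention,
       topGroup = topGroup, groupDiff = groupDiff,
       lambdaChosen = lambdaChosen,
       predictions = data.frame(subject = subject, y = y, score = scores))
}

#' Group of most-important features by ANOVA and Tukey comparison
#'
#' One-way ANOVA of per-fold retention proportions across features, followed
#' by Tukey honest-significant-difference comparisons (family level 0.05):
#' the top group contains the feature with maximal mean retention and every
#' feature not significantly different from it. With (near-)zero residual
#' variance the comparison degenerates: features with mean retention equal to
#' the maximum form the group (all features, with a warning, when everything
#' is identical).
#'
#' @param retentionPerFold folds x features matrix of retention proportions.
#' @return list with `topGroup` (feature names), `meanRetention`, `anovaP`.
#' @export
groupTopFeatures <- function(retentionPerFold) {
  stopifnot(is.matrix(retentionPerFold), nrow(retentionPerFold) >= 2L)
  feats <- colnames(retentionPerFold)
  if (is.null(feats)) feats <- paste0("C", seq_len(ncol(retentionPerFold)))
  mr <- colMeans(retentionPerFold)
  best <- feats[which.max(mr)]
  df <- data.frame(
    retention = as.vector(retentionPerFold),
    feature = factor(rep(feats, each = nrow(retentionPerFold)), levels = feats))
  if (stats::var(df$retention) < 1e-14) {
    warning("retention is identical everywhere; returning all features")
    return(list(topGroup = feats, meanRetention = mr, anovaP = NA_real_))
  }
  fit <- stats::aov(retention ~ feature, data = df)
  resid_ms <- sum(stats::residuals(fit)^2) / fit$df.residual
  if (resid_ms < 1e-14) {
    top <- feats[abs(mr - max(mr)) < 1e-12]
    return(list(topGroup = top, meanRetention = mr,
                anovaP = suppressWarnings(stats::anova(fit)[["Pr(>F)"]][1])))
  }
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$feature
  cmp <- rownames(tk)
  inTop <- vapply(feats, function(f) {
    if (f == best) return(TRUE)
    row <- match(paste(f, best, sep = "-"), cmp)
    if (is.na(row)) row <- match(paste(best, f, sep = "-"), cmp)
    tk[row, "p adj"] >= 0.05
  }, logical(1))
  list(topGroup = feats[inTop], meanRetention = mr,
       anovaP = stats::anova(fit)[["Pr(>F)"]][1])
}

#' Group differences over selected features
#'
#' Welch two-sample t-test per selected feature with Benjamini-Hochberg
#' correction within the selected set. Direction is
#' `sign(mean(HC) - mean(SZ))`: negative means stronger connectivity in SZ.
#' A feature constant within both groups gets p = 1 by convention (noted).
#'
#' @param ds dataset from [buildStateDataset()].
#' @param features feature names to test (e.g. the top group).
#' @return data.frame: `feature`, `direction`, `meanHC`, `meanSZ`, `p`, `q`,
#'   `degenerate`.
#' @export
groupDifferenceTest <- function(ds, features) {
  stopifnot(all(features %in% colnames(ds$X)))
  hc <- ds$y == "HC"
  res <- lapply(features, function(f) {
    a <- ds$X[hc, f]; b <- ds$X[!hc, f]
    degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
    p <- if (degenerate) 1 else stats::t.test(a, b)$p.value
    data.frame(feature = f, direction = sign(mean(a) - mean(b)),
               meanHC = mean(a), meanSZ = mean(b), p = p,
               degenerate = degenerate)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$q, out$p), c("feature", "direction", "meanHC", "meanSZ",
                             "p", "q", "degenerate")]
}
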