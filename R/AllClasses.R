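#' @import methods
NULL

setClassUnion("list_OR_NULL", c("list", "NULL"))

#' Configuration of a synthetic dFC cohort
#'
#' Parameters of the hidden-Markov covariance-switching generative model used
#' by [generateCohort()]: group sizes, node and state counts, per-group
#' state-conditional covariances and transition matrices, the planted
#' symptom-transition coupling, and covariate distributions. Build with
#' [cohortConfig()] or take the frozen preset [defaultCohortConfig()].
#'
#' @slot nHC,nSZ number of control / patient subjects.
#' @slot nNodes number of network nodes (C).
#' @slot nStates number of hidden connectivity states (K).
#' @slot nTimepoints scan length per subject, in TRs.
#' @slot trSeconds repetition time in seconds.
#' @slot stateCovariances list with elements `hc` and `sz`, each a list of
#'   `nStates` positive-semidefinite `nNodes x nNodes` matrices.
#' @slot transitionMatrices list with elements `hc` and `sz`, each a
#'   row-stochastic `nStates x nStates` matrix indexed `[from, to]`.
#' @slot symptomLink list: `from`, `to` (states), `targetR` (expected Pearson
#'   correlation between the subject's empirical transition probability and the
#'   linked symptom scale), `noiseSd` (residual SD of the score, raw units),
#'   `scale` (name of the linked scale), `base` (scale mean).
#' @slot covariateModel list: `ageMean`, `ageSd`, `maleFraction`, `nSites`.
#' @slot missingFraction fraction of SZ subjects with missing symptom scores.
#' @slot nodeNames,nodeGroups node labels and the anatomical grouping
#'   (named list of node-name vectors) used for block summaries.
#' @slot seed integer seed making generation fully reproducible.
#' @export
setClass("CohortConfig",
  representation(
    nHC = "integer", nSZ = "integer", nNodes = "integer",
    nStates = "integer", nTimepoints = "integer", trSeconds = "numeric",
    stateCovariances = "list", transitionMatrices = "list",
    symptomLink = "list", covariateModel = "list",
    missingFraction = "numeric", nodeNames = "character",
    nodeGroups = "list", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  C <- object@nNodes
  K <- object@nStates
  if (object@nHC < 1L || object@nSZ < 1L) msg <- c(msg, "both groups need at least one subject")
  if (object@nTimepoints < 22L)
    msg <- c(msg, "nTimepoints must exceed the downstream window length (>= 22)")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  for (g in c("hc", "sz")) {
    covs <- object@stateCovariances[[g]]
    if (length(covs) != K) {
      msg <- c(msg, sprintf("stateCovariances$%s must hold %d matrices", g, K))
      next
    }
    for (k in seq_len(K)) {
      S <- covs[[k]]
      if (!is.matrix(S) || any(dim(S) != C)) {
        msg <- c(msg, sprintf("state %d (%s): covariance is not %dx%d", k, g, C, C))
      } else if (max(abs(S - t(S))) > 1e-8) {
        msg <- c(msg, sprintf("state %d (%s): covariance is not symmetric", k, g))
      } else if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
        msg <- c(msg, sprintf("state %d (%s): covariance is not positive semidefinite", k, g))
      }
    }
    P <- object@transitionMatrices[[g]]
    if (!is.matrix(P) || any(dim(P) != K)) {
      msg <- c(msg, sprintf("transitionMatrices$%s must be %dx%d", g, K, K))
    } else if (any(P < 0) || max(abs(rowSums(P) - 1)) > 1e-12) {
      msg <- c(msg, sprintf("transitionMatrices$%s rows must sum to 1 within 1e-12", g))
    }
  }
  lk <- object@symptomLink
  if (abs(lk$targetR) >= 1) msg <- c(msg, "symptomLink targetR must lie in (-1, 1)")
  if (lk$noiseSd <= 0) msg <- c(msg, "symptomLink noiseSd must be positive")
  if (lk$from < 1 || lk$from > K || lk$to < 1 || lk$to > K)
    msg <- c(msg, "symptomLink states out of range")
  if (length(object@nodeNames) != C) msg <- c(msg, "nodeNames length must equal nNodes")
  if (!all(unlist(object@nodeGroups) %in% object@nodeNames))
    msg <- c(msg, "nodeGroups refers to unknown nodes")
  if (object@missingFraction < 0 || object@missingFraction >= 1)
    msg <- c(msg, "missingFraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Cohort of per-subject node time courses
#'
#' The central container: one signal matrix (timepoints x nodes) per subject
#' plus subject-level metadata (group, covariates, symptom scores). Synthetic
#' cohorts additionally carry the generator's ground truth (hidden state
#' sequences, true transition matrices, planted link) in `truth`.
#'
#' @slot signals named list of numeric matrices, one per subject, each
#'   `nTimepoints x nNodes` with common column order.
#' @slot subjects a [S4Vectors::DataFrame] with one row per subject:
#'   `id`, `group` (factor HC/SZ), `age`, `gender`, `site`, and the symptom
#'   scales (`panss_positive`, `panss_negative`, `panss_total`; NA when
#'   missing or for controls).
#' @slot nodeNames common node (column) labels.
#' @slot trSeconds repetition time in seconds, shared by all subjects.
#' @slot truth list of generator ground truth (empty for ingested data).
#' @export
setClass("TimeCourseSet",
  representation(
    signals = "list", subjects = "DataFrame", nodeNames = "character",
    trSeconds = "numeric", truth = "list"
  )
)

setValidity("TimeCourseSet", function(object) {
  msg <- character()
  n <- length(object@signals)
  if (nrow(object@subjects) != n)
    msg <- c(msg, "subjects table and signals list disagree on subject count")
  if (!all(c("id", "group") %in% colnames(object@subjects)))
    msg <- c(msg, "subjects table needs 'id' and 'group' columns")
  if (n > 0) {
    C <- length(object@nodeNames)
    ok <- vapply(object@signals, function(x)
      is.matrix(x) && ncol(x) == C && all(is.finite(x)), logical(1))
    if (!all(ok))
      msg <- c(msg, sprintf("signals must be finite matrices with %d columns (bad: %s)",
                            C, paste(names(object@signals)[!ok], collapse = ", ")))
    if (!identical(sort(names(object@signals)), sort(as.character(object@subjects$id))))
      msg <- c(msg, "signal names must match subject ids")
    if (nlevels(factor(object@subjects$group)) > 2)
      msg <- c(msg, "group labels must come from exactly two categories")
  }
  if (length(object@trSeconds) != 1 || object@trSeconds <= 0)
    msg <- c(msg, "trSeconds must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Tapered sliding-window specification
#'
#' Weight profile of the sliding window: a rectangle spanning `windowTRs` TR
#' intervals smoothed by convolution with a Gaussian kernel of standard
#' deviation `sigmaSeconds`, cropped to its central `windowTRs + 1` samples and
#' normalized to unit sum. Build with [buildTaper()].
#'
#' @slot weights numeric vector of length `windowTRs + 1`, symmetric,
#'   nonnegative, summing to 1.
#' @slot windowTRs nominal window size L in TRs (support spans L TR intervals,
#'   i.e. L + 1 samples).
#' @slot sigmaSeconds Gaussian smoothing SD in seconds.
#' @slot trSeconds repetition time in seconds.
#' @export
setClass("TaperSpec",
  representation(weights = "numeric", windowTRs = "integer",
                 sigmaSeconds = "numeric", trSeconds = "numeric")
)

setValidity("TaperSpec", function(object) {
  w <- object@weights
  msg <- character()
  if (length(w) != object@windowTRs + 1L)
    msg <- c(msg, "weights must have length windowTRs + 1")
  if (any(w < 0)) msg <- c(msg, "weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-12) msg <- c(msg, "weights must sum to 1")
  if (max(abs(w - rev(w))) > 1e-10) msg <- c(msg, "weights must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Windowed connectivity features for a cohort
#'
#' Per subject, the vectorized tapered sliding-window connectivity: a
#' `T x P` matrix where `T = nTimepoints - windowTRs` windows and
#' `P = C(C-1)/2` node-pair features in strict upper-triangle, row-wise order.
#' Build with [computeDFC()].
#'
#' @slot features named list of `T x P` matrices, one per subject.
#' @slot featureIndex data.frame mapping feature column to its node pair:
#'   columns `feature`, `nodeA`, `nodeB`, `name`.
#' @slot nodeNames node labels in manifest column order.
#' @slot stat `"covariance"` or `"correlation"` (within-window statistic).
#' @slot windowTRs window size L used.
#' @export
setClass("DFCSet",
  representation(features = "list", featureIndex = "data.frame",
                 nodeNames = "character", stat = "character",
                 windowTRs = "integer")
)

setValidity("DFCSet", function(object) {
  msg <- character()
  P <- nrow(object@featureIndex)
  C <- length(object@nodeNames)
  if (P != C * (C - 1) / 2) msg <- c(msg, "featureIndex must have C(C-1)/2 rows")
  ok <- vapply(object@features, function(x) is.matrix(x) && ncol(x) == P &&
                 all(is.finite(x)), logical(1))
  if (!all(ok)) msg <- c(msg, "every feature matrix must be finite with P columns")
  if (!object@stat %in% c("covariance", "correlation"))
    msg <- c(msg, "stat must be 'covariance' or 'correlation'")
  if (length(msg)) msg else TRUE
})

#' Fitted connectivity-state model
#'
#' Result of correlation-distance k-means over pooled windows: K centroid
#' connectivity patterns, per-subject state sequences, and (when K was chosen
#' by the elbow criterion) the within/between distance-ratio curve with its
#' knee strength. Build with [clusterStates()].
#'
#' @slot nStates number of states K.
#' @slot centroids `K x P` matrix of state centroids in feature space.
#' @slot assignments named list of integer state sequences (1-based, length T)
#'   per subject.
#' @slot inertiaCurve data.frame with columns `k` and `ratio` (mean
#'   within-cluster distance over mean between-centroid distance), empty when
#'   K was fixed by the caller.
#' @slot kneeStrength normalized second-difference of the ratio curve at the
#'   selected K (NA when K was fixed); small values flag a weak elbow.
#' @slot distance distance metric used (`"correlation"`).
#' @slot totWithin total within-cluster distance of the best replicate.
#' @slot seed seed used for replicate initialization.
#' @export
setClass("StateModel",
  representation(nStates = "integer", centroids = "matrix",
                 assignments = "list", inertiaCurve = "data.frame",
                 kneeStrength = "numeric", distance = "character",
                 totWithin = "numeric", seed = "integer")
)

setValidity("StateModel", function(object) {
  msg <- character()
  K <- object@nStates
  if (K < 1L) msg <- c(msg, "nStates must be >= 1")
  if (nrow(object@centroids) != K) msg <- c(msg, "centroids must have K rows")
  bad <- vapply(object@assignments, function(s)
    any(s < 1L | s > K), logical(1))
  if (any(bad)) msg <- c(msg, "state assignments must lie in 1..K")
  if (length(msg)) msg else TRUE
})

#' Per-subject state-transition features
#'
#' For each subject the empirical first-order transition-probability matrix
#' estimated from the state sequence, flattened to K^2 named features
#' (`P(j->i)` = probability of moving from state j to state i). Rows of the
#' transition matrix for states never occupied before the final window are
#' zero, flagged, and reported as NA in the flattened feature matrix so that
#' downstream correlations drop them pairwise. Build with
#' [transitionFeatures()].
#'
#' @slot matrices named list of `K x K` matrices indexed `[from, to]`.
#' @slot visitCounts named list of K-vectors: times each state was occupied
#'   before the final window.
#' @slot featureMatrix subjects x K^2 matrix of flattened probabilities with
#'   NA for flagged (unvisited origin state) entries.
#' @slot nStates number of states K.
#' @export
setClass("TransitionSet",
  representation(matrices = "list", visitCounts = "list",
                 featureMatrix = "matrix", nStates = "integer")
)

setValidity("TransitionSet", function(object) {
  msg <- character()
  K <- object@nStates
  if (ncol(object@featureMatrix) != K * K)
    msg <- c(msg, "featureMatrix must have K^2 columns")
  if (nrow(object@featureMatrix) != length(object@matrices))
    msg <- c(msg, "featureMatrix rows must match the number of subjects")
  for (tm in object@matrices) {
    if (any(tm < -1e-12 | tm > 1 + 1e-12)) {
      msg <- c(msg, "transition probabilities must lie in [0, 1]")
      break
    }
  }
  if (length(msg)) msg else TRUE
})
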