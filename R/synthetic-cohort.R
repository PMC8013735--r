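#' Build a synthetic-cohort configuration
#'
#' Assembles and validates a [CohortConfig-class] for the hidden-Markov
#' covariance-switching generator. Subject signals are zero-mean Gaussian
#' conditional on a hidden connectivity state; the state evolves as a
#' first-order Markov chain (uniform initial distribution) with a per-group
#' transition matrix; group contrasts are planted as cell-wise differences
#' between the HC and SZ state covariances; one symptom scale is coupled to a
#' chosen transition probability at a target correlation.
#'
#' @param nHC,nSZ subjects per group.
#' @param nNodes number of nodes C.
#' @param nStates number of hidden states K.
#' @param nTimepoints timepoints per subject.
#' @param trSeconds repetition time (s).
#' @param stateCovariances list with `hc` and `sz` elements, each a list of K
#'   positive-semidefinite C x C matrices.
#' @param transitionMatrices list with `hc` and `sz` row-stochastic K x K
#'   matrices indexed `[from, to]`.
#' @param symptomLink list with `from`, `to`, `targetR`, `noiseSd`, and
#'   optionally `scale` (default `"panss_total"`) and `base` (scale mean).
#' @param covariateModel list with `ageMean`, `ageSd`, `maleFraction`,
#'   `nSites`, `siteEffect` (additive per-site shift of the linked score; 0 =
#'   no confound).
#' @param missingFraction fraction of SZ subjects with missing symptom scores.
#' @param nodeNames,nodeGroups node labels and anatomical grouping.
#' @param seed integer seed.
#' @return a validated [CohortConfig-class].
#' @seealso [defaultCohortConfig()], [generateCohort()]
#' @export
cohortConfig <- function(nHC, nSZ, nNodes, nStates, nTimepoints = 144L,
                         trSeconds = 2, stateCovariances, transitionMatrices,
                         symptomLink, covariateModel = list(),
                         missingFraction = 0, nodeNames = NULL,
                         nodeGroups = list(), seed = 1L) {
  if (is.null(nodeNames)) nodeNames <- paste0("node", seq_len(nNodes))
  cm <- utils::modifyList(
    list(ageMean = 38, ageSd = 12, maleFraction = 0.72, nSites = 1L,
         siteEffect = 0),
    covariateModel)
  lk <- utils::modifyList(
    list(scale = "panss_total", base = 58),
    symptomLink)
  new("CohortConfig",
      nHC = as.integer(nHC), nSZ = as.integer(nSZ),
      nNodes = as.integer(nNodes), nStates = as.integer(nStates),
      nTimepoints = as.integer(nTimepoints), trSeconds = trSeconds,
      stateCovariances = stateCovariances,
      transitionMatrices = transitionMatrices,
      symptomLink = lk, covariateModel = cm,
      missingFraction = missingFraction, nodeNames = nodeNames,
      nodeGroups = nodeGroups, seed = as.integer(seed))
}

# Five near-orthogonal +/-1 loading patterns over 7 nodes (rows 2..6 of an
# order-8 Hadamard matrix with the constant column dropped). Rank-one loadings
# lambda = scale * h give state covariances sigma0^2 I + lambda lambda' whose
# vectorized off-diagonal patterns are pairwise nearly uncorrelated, i.e.
# well-separated k-means centroids.
.stateLoadingSigns <- function() {
  h2 <- matrix(c(1, 1, 1, -1), 2, 2)
  h8 <- kronecker(h2, kronecker(h2, h2))
  h8[2:6, 2:8, drop = FALSE]
}

.defaultNodeNames <- c("PCu1", "PCu2", "ACC1", "PCC1", "ACC2", "PCu3", "PCC2")
.defaultNodeGroups <- list(PCu = c("PCu1", "PCu2", "PCu3"),
                           ACC = c("ACC1", "ACC2"),
                           PCC = c("PCC1", "PCC2"))

# Ensure min eigenvalue >= floor by inflating the diagonal (deterministic).
.psdFloor <- function(S, floor = 0.05) {
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < floor) S <- S + diag(floor - ev, nrow(S))
  S
}

#' Frozen default cohort preset
#'
#' A documented preset emulating a single-site resting-state schizophrenia
#' cohort: 7 default-mode subnodes (three precuneus, two anterior cingulate,
#' two posterior cingulate), 5 well-separated connectivity states, 144
#' usable timepoints at TR = 2 s (149 acquired volumes minus 5 discarded dummy
#' scans), and COBRE-like group sizes (89 HC, 68 SZ). State covariances are
#' unit-variance rank-one patterns from near-orthogonal sign loadings
#' (between-state centroid correlations below 0.3 after vectorization), with
#' planted group contrasts: precuneus-posterior-cingulate (PCu/PCC) coupling
#' higher in SZ in states 1 and 4, anterior-cingulate (ACC) coupling higher in
#' HC in states 2 and 4. State chains are sticky (self-transition 0.985; mean
#' dwell about 130 s), except that SZ subjects enter state 2 more often and
#' leave it faster, with the exit toward state 4 elevated relative to HC; the
#' PANSS-total score of SZ subjects is coupled to the subject's empirical
#' 2->4 transition probability at target r = 0.40.
#'
#' @param nHC,nSZ group sizes (defaults 89 and 68).
#' @param nTimepoints timepoints per subject (default 144).
#' @param targetR planted symptom-link correlation (default 0.40).
#' @param missingFraction fraction of SZ subjects with missing scores
#'   (default 0.06, emulating scores available for 64 of 68 patients).
#' @param nullEffects if `TRUE`, both groups share the HC covariances and
#'   transition matrix and the symptom link is removed (scores become pure
#'   noise) — a null cohort for type-I-error checks.
#' @param nSites,siteEffect number of acquisition sites and an optional
#'   additive per-site shift of the linked score (a plantable site confound;
#'   default none).
#' @param seed integer seed.
#' @return a [CohortConfig-class].
#' @export
defaultCohortConfig <- function(nHC = 89L, nSZ = 68L, nTimepoints = 144L,
                                targetR = 0.40, missingFraction = 0.06,
                                nullEffects = FALSE, nSites = 1L,
                                siteEffect = 0, seed = 1L) {
  C <- 7L; K <- 5L
  H <- .stateLoadingSigns()
  covHC <- lapply(seq_len(K), function(k) {
    lam <- 0.8 * H[k, ]
    S <- diag(1 - 0.8^2, C) + tcrossprod(lam)
    dimnames(S) <- list(.defaultNodeNames, .defaultNodeNames)
    S
  })
  covSZ <- covHC
  pcu <- match(.defaultNodeGroups$PCu, .defaultNodeNames)
  acc <- match(.defaultNodeGroups$ACC, .defaultNodeNames)
  pcc <- match(.defaultNodeGroups$PCC, .defaultNodeNames)
  bump <- function(S, rows, cols, delta) {
    S[rows, cols] <- S[rows, cols] + delta
    S[cols, rows] <- t(S[rows, cols])
    S
  }
  for (k in c(1L, 4L))  # PCu/PCC coupling higher in SZ
    covSZ[[k]] <- bump(covSZ[[k]], pcu, pcc, +0.15)
  for (k in c(2L, 4L))  # ACC coupling higher in HC
    covSZ[[k]] <- bump(covSZ[[k]], acc[1], acc[2], -0.15)
  covSZ <- lapply(covSZ, .psdFloor)

  Phc <- matrix(0.00375, K, K); diag(Phc) <- 0.985
  # SZ dynamics: state 2 entered more often and left faster, with the exit
  # toward state 4 elevated — the substrate of the planted symptom link.
  Psz <- Phc
  for (j in c(1L, 3L, 4L, 5L)) {
    Psz[j, 2L] <- 0.0075
    Psz[j, j] <- 1 - 0.0075 - 3 * 0.00375
  }
  Psz[2L, ] <- c(0.02, 0.90, 0.02, 0.04, 0.02)
  cfg <- cohortConfig(
    nHC = nHC, nSZ = nSZ, nNodes = C, nStates = K,
    nTimepoints = nTimepoints, trSeconds = 2,
    stateCovariances = list(hc = covHC, sz = if (nullEffects) covHC else covSZ),
    transitionMatrices = list(hc = Phc, sz = if (nullEffects) Phc else Psz),
    symptomLink = list(from = 2L, to = 4L,
                       targetR = if (nullEffects) 0 else targetR,
                       noiseSd = 15, scale = "panss_total", base = 58),
    covariateModel = list(nSites = as.integer(nSites), siteEffect = siteEffect),
    missingFraction = missingFraction,
    nodeNames = .defaultNodeNames, nodeGroups = .defaultNodeGroups,
    seed = seed)
  cfg
}

# Sample one state sequence from a row-stochastic chain, uniform start.
.sampleChain <- function(P, n) {
  K <- nrow(P)
  s <- integer(n)
  s[1] <- sample.int(K, 1L)
  if (n > 1) {
    u <- stats::runif(n - 1L)
    cum <- t(apply(P, 1, cumsum))
    for (t in 2:n) {
      s[t] <- findInterval(u[t - 1L], cum[s[t - 1L], ], left.open = TRUE) + 1L
    }
  }
  s
}

# Empirical P(from -> to) of a sequence; NA when 'from' unoccupied before the end.
.empiricalTransition <- function(s, from, to) {
  idx <- which(s[-length(s)] == from)
  if (!length(idx)) return(NA_real_)
  mean(s[idx + 1L] == to)
}

#' Generate a synthetic cohort
#'
#' Draws a [TimeCourseSet-class] from the covariance-switching model in a
#' [CohortConfig-class]: per subject, a hidden state sequence from the group's
#' Markov chain (uniform initial distribution), then each timepoint's node
#' vector from a zero-mean Gaussian with the active state's covariance.
#' SZ symptom scores on the linked scale are built as
#' `base + a * Phat(from->to) + noise`, with the slope `a` calibrated against
#' the cohort's empirical spread of `Phat` so that the correlation between the
#' subject's true transition probability and the emitted score equals
#' `targetR` in expectation. Ground truth (state sequences, transition
#' matrices, per-subject `Phat`, link parameters) is embedded in `truth`.
#' Fully reproducible from `config@seed`.
#'
#' @param config a validated [CohortConfig-class].
#' @return a [TimeCourseSet-class] with ground truth attached.
#' @examples
#' cohort <- generateCohort(defaultCohortConfig(nHC = 4, nSZ = 4, targetR = 0,
#'                                              seed = 7))
#' cohort
#' @export
generateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  K <- config@nStates; C <- config@nNodes; N <- config@nTimepoints
  cm <- config@covariateModel
  lk <- config@symptomLink

  groups <- c(rep("HC", config@nHC), rep("SZ", config@nSZ))
  n <- length(groups)
  ids <- sprintf("sub%03d", seq_len(n))
  chol_g <- lapply(config@stateCovariances, function(covs)
    lapply(covs, function(S) chol(.psdFloor(S, 1e-10))))

  sigs <- vector("list", n); names(sigs) <- ids
  seqs <- vector("list", n); names(seqs) <- ids
  for (i in seq_len(n)) {
    g <- tolower(groups[i])
    s <- .sampleChain(config@transitionMatrices[[g]], N)
    z <- matrix(stats::rnorm(N * C), N, C)
    x <- matrix(0, N, C, dimnames = list(NULL, config@nodeNames))
    for (k in seq_len(K)) {
      rows <- which(s == k)
      if (length(rows)) x[rows, ] <- z[rows, , drop = FALSE] %*% chol_g[[g]][[k]]
    }
    sigs[[i]] <- x
    seqs[[i]] <- s
  }

  age <- pmin(65, pmax(18, round(stats::rnorm(n, cm$ageMean, cm$ageSd))))
  gender <- factor(ifelse(stats::runif(n) < cm$maleFraction, "M", "F"),
                   levels = c("F", "M"))
  site <- factor(sprintf("site%d", sample.int(cm$nSites, n, replace = TRUE)))

  # Symptom scores: SZ only; linked scale coupled to the subject's empirical
  # transition probability, remaining scales independent noise.
  sz <- which(groups == "SZ")
  phat <- vapply(seqs[sz], .empiricalTransition, numeric(1),
                 from = lk$from, to = lk$to)
  scores <- data.frame(panss_positive = rep(NA_real_, n),
                       panss_negative = rep(NA_real_, n),
                       panss_total = rep(NA_real_, n))
  scores$panss_positive[sz] <- pmin(49, pmax(7, round(stats::rnorm(length(sz), 15.3, 5))))
  scores$panss_negative[sz] <- pmin(49, pmax(7, round(stats::rnorm(length(sz), 14.5, 5.4))))
  linked <- stats::rnorm(length(sz), lk$base, lk$noiseSd)
  if (lk$targetR != 0) {
    usable <- is.finite(phat)
    sdP <- stats::sd(phat[usable])
    if (!isTRUE(sdP > 0))
      stop("symptom link target r = ", lk$targetR, " is infeasible: the ",
           "empirical transition probability P(", lk$from, "->", lk$to,
           ") has zero spread across SZ subjects")
    a <- lk$noiseSd * lk$targetR / (sdP * sqrt(1 - lk$targetR^2))
    linked[usable] <- linked[usable] + a * (phat[usable] - mean(phat[usable]))
  }
  if (cm$siteEffect != 0 && cm$nSites > 1L)
    linked <- linked + cm$siteEffect * (as.integer(site[sz]) - 1L)
  scores[[lk$scale]][sz] <- round(linked)

  if (config@missingFraction > 0) {
    drop <- sz[stats::runif(length(sz)) < config@missingFraction]
    scores[drop, ] <- NA_real_
  }

  subjects <- S4Vectors::DataFrame(
    id = ids, group = factor(groups, levels = c("HC", "SZ")),
    age = age, gender = gender, site = site,
    panss_positive = scores$panss_positive,
    panss_negative = scores$panss_negative,
    panss_total = scores$panss_total)

  new("TimeCourseSet", signals = sigs, subjects = subjects,
      nodeNames = config@nodeNames, trSeconds = config@trSeconds,
      truth = list(stateSequences = seqs,
                   transitionMatrices = config@transitionMatrices,
                   stateCovariances = config@stateCovariances,
                   linkPhat = stats::setNames(phat, ids[sz]),
                   symptomLink = lk,
                   nodeGroups = config@nodeGroups,
                   nStates = K))
}

#' True per-window state labels of a synthetic cohort
#'
#' Reduces each subject's hidden per-timepoint state sequence to one label per
#' sliding window by taper-weighted majority vote over the window's support —
#' the ground-truth counterpart of the window assignments produced by
#' [clusterStates()].
#'
#' @param cohort a synthetic [TimeCourseSet-class] (with ground truth).
#' @param taper the [TaperSpec-class] used for the windows.
#' @return named list of integer label vectors, length `nTimepoints - L`.
#' @export
trueWindowStates <- function(cohort, taper) {
  stopifnot(is(cohort, "TimeCourseSet"), is(taper, "TaperSpec"))
  if (!length(cohort@truth))
    stop("cohort carries no ground truth (not synthetic)")
  w <- taper@weights
  L <- taper@windowTRs
  K <- cohort@truth$nStates
  lapply(cohort@truth$stateSequences, function(s) {
    nT <- length(s) - L
    if (nT < 1) stop("state sequence shorter than the window")
    out <- integer(nT)
    for (t in seq_len(nT)) {
      seg <- s[t:(t + L)]
      votes <- vapply(seq_len(K), function(k) sum(w[seg == k]), numeric(1))
      out[t] <- which.max(votes)
    }
    out
  })
}
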