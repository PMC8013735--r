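#' Build the tapered window
#'
#' Constructs the sliding-window weight profile: a unit rectangle spanning
#' `windowTRs` TR intervals (i.e. `windowTRs + 1` samples — 40 s at L = 20,
#' TR = 2 s) convolved with a unit-mass Gaussian kernel of standard deviation
#' `sigmaSeconds`, cropped to its central `windowTRs + 1` samples and
#' renormalized to unit sum. The Gaussian is sampled on an integer grid out to
#' four standard deviations before convolution (truncation error below 1e-4,
#' immaterial after cropping).
#'
#' @param windowTRs window size L in TRs (default 20).
#' @param sigmaSeconds Gaussian SD in seconds (default 3).
#' @param trSeconds repetition time in seconds (default 2).
#' @return a [TaperSpec-class].
#' @examples
#' taper <- buildTaper(20, 3, 2)
#' length(taperWeights(taper))  # 21
#' @export
buildTaper <- function(windowTRs = 20L, sigmaSeconds = 3, trSeconds = 2) {
  windowTRs <- as.integer(windowTRs)
  if (windowTRs < 2L) stop("windowTRs must be >= 2")
  if (sigmaSeconds <= 0) stop("sigmaSeconds must be positive")
  if (trSeconds <= 0) stop("trSeconds must be positive")
  s <- sigmaSeconds / trSeconds             # SD in samples
  m <- max(1L, ceiling(4 * s))
  kern <- stats::dnorm(seq(-m, m), sd = s)
  kern <- kern / sum(kern)
  rect <- rep(1, windowTRs + 1L)
  full <- stats::convolve(rect, rev(kern), type = "open")  # length L + 1 + 2m
  start <- m + 1L
  w <- full[start:(start + windowTRs)]
  w <- w / sum(w)
  new("TaperSpec", weights = w, windowTRs = windowTRs,
      sigmaSeconds = sigmaSeconds, trSeconds = trSeconds)
}

# Feature index for C nodes: strict upper triangle, row-wise (i < j).
.pairIndex <- function(nodeNames) {
  C <- length(nodeNames)
  ij <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  data.frame(feature = seq_len(nrow(ij)),
             nodeA = nodeNames[ij[, 1]], nodeB = nodeNames[ij[, 2]],
             name = paste0(nodeNames[ij[, 1]], "-", nodeNames[ij[, 2]]),
             stringsAsFactors = FALSE)
}

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the strict upper triangle in row-wise order (i < j, lexicographic
#' by node order) — the C(C-1)/2 pairwise features; 21 for 7 nodes.
#' `devectorizeFC()` is the inverse, restoring the off-diagonal entries
#' exactly with the diagonal set to 0 by convention.
#'
#' @param mat square symmetric numeric matrix.
#' @param v feature vector of length C(C-1)/2.
#' @param nodeNames optional node labels for the rebuilt matrix.
#' @return `vectorizeFC`: numeric vector; `devectorizeFC`: symmetric matrix
#'   with zero diagonal.
#' @examples
#' vectorizeFC(diag(7))  # 21 zeros
#' @export
vectorizeFC <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("input must be a square matrix")
  if (max(abs(mat - t(mat))) > 1e-8) stop("input must be symmetric")
  tm <- t(mat)                      # row-wise upper triangle
  tm[lower.tri(tm)]
}

#' @rdname vectorizeFC
#' @export
devectorizeFC <- function(v, nodeNames = NULL) {
  C <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (C != round(C)) stop("length is not C(C-1)/2 for any integer C")
  C <- as.integer(C)
  M <- matrix(0, C, C)
  M[lower.tri(M)] <- v
  M <- t(M)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  if (!is.null(nodeNames)) dimnames(M) <- list(nodeNames, nodeNames)
  M
}

# Taper-weighted covariance (or correlation) of one window, unbiased under
# reliability weights: sum_i w_i (x_i - mu)(x_i - mu)' / (1 - sum w_i^2).
.weightedFC <- function(seg, w, corr = FALSE) {
  mu <- colSums(seg * w)
  xc <- sweep(seg, 2, mu)
  S <- crossprod(xc * w, xc) / (1 - sum(w^2))
  if (corr) {
    d <- sqrt(diag(S))
    d[d == 0] <- Inf                 # zero-variance node -> zero correlation
    S <- S / outer(d, d)
    diag(S) <- ifelse(is.infinite(d), 0, 1)
  }
  S
}

#' Tapered sliding-window connectivity of one signal matrix
#'
#' Slides the taper along the (per-series z-scored) signal with unit step and
#' computes, at each of `T = nTimepoints - L` start positions, the
#' taper-weighted covariance (default) or correlation over the window's
#' `L + 1`-sample support, vectorized to the strict upper triangle. Each
#' column is z-scored over the whole series first so feature scales are
#' comparable across subjects; constant columns are left at zero.
#'
#' @param signal numeric matrix, timepoints x nodes, all finite.
#' @param taper a [TaperSpec-class].
#' @param stat `"covariance"` (default) or `"correlation"`.
#' @return list with `features` (T x P matrix) and `featureIndex`.
#' @export
slidingDFC <- function(signal, taper, stat = c("covariance", "correlation")) {
  stat <- match.arg(stat)
  stopifnot(is(taper, "TaperSpec"))
  if (!is.matrix(signal) || !all(is.finite(signal)))
    stop("signal must be a finite numeric matrix")
  L <- taper@windowTRs
  N <- nrow(signal)
  if (N < L + 1L)
    stop("signal has ", N, " timepoints; at least ", L + 1L,
         " are required for a window of L = ", L, " TRs")
  nodeNames <- colnames(signal)
  if (is.null(nodeNames)) nodeNames <- paste0("node", seq_len(ncol(signal)))
  z <- scale(signal)
  z[, attr(z, "scaled:scale") == 0] <- 0   # constant nodes stay zero
  w <- taper@weights
  nT <- N - L
  idx <- .pairIndex(nodeNames)
  feats <- matrix(NA_real_, nT, nrow(idx),
                  dimnames = list(NULL, idx$name))
  for (t in seq_len(nT)) {
    S <- .weightedFC(z[t:(t + L), , drop = FALSE], w, corr = stat == "correlation")
    feats[t, ] <- t(S)[lower.tri(S)]
  }
  list(features = feats, featureIndex = idx)
}

#' Windowed connectivity for every subject of a cohort
#'
#' Applies [slidingDFC()] to each subject of a [TimeCourseSet-class] and
#' collects the results into a [DFCSet-class].
#'
#' @param cohort a [TimeCourseSet-class].
#' @param taper a [TaperSpec-class]; default `buildTaper()` with the cohort's
#'   TR.
#' @param stat `"covariance"` or `"correlation"`.
#' @return a [DFCSet-class].
#' @examples
#' cohort <- generateCohort(defaultCohortConfig(nHC = 2, nSZ = 2, targetR = 0,
#'                                              seed = 1))
#' dfc <- computeDFC(cohort)
#' dfc
#' @export
computeDFC <- function(cohort, taper = buildTaper(trSeconds = trSeconds(cohort)),
                       stat = c("covariance", "correlation")) {
  stat <- match.arg(stat)
  stopifnot(is(cohort, "TimeCourseSet"))
  out <- lapply(signals(cohort), slidingDFC, taper = taper, stat = stat)
  new("DFCSet",
      features = lapply(out, `[[`, "features"),
      featureIndex = out[[1]]$featureIndex,
      nodeNames = nodeNames(cohort), stat = stat,
      windowTRs = taper@windowTRs)
}
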