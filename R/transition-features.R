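#' Empirical state-transition probability matrix
#'
#' Maximum-likelihood first-order transition frequencies of a state sequence:
#' `matrix[j, i] = #\{t : s(t) = j, s(t+1) = i\} / #\{t < T : s(t) = j\}`.
#' Rows for states never occupied before the final element are all-zero and
#' flagged via a zero visit count (no smoothing; downstream analyses drop
#' flagged features pairwise).
#'
#' @param seq integer state sequence (values in 1..k), length at least 2.
#' @param k number of states.
#' @return list with `matrix` (k x k, indexed `[from, to]`), `visitCounts`
#'   (times each state was occupied before the final element), and
#'   `unvisited` (logical flags).
#' @examples
#' transitionMatrix(c(1, 2, 1, 2, 1), k = 2)$matrix
#' @export
transitionMatrix <- function(seq, k) {
  seq <- as.integer(seq)
  if (length(seq) < 2L) stop("state sequence must have length >= 2")
  if (any(seq < 1L | seq > k)) stop("state values must lie in 1..", k)
  lv <- seq_len(k)
  counts <- table(factor(seq[-length(seq)], levels = lv),
                  factor(seq[-1L], levels = lv))
  counts <- matrix(as.numeric(counts), k, k,
                   dimnames = list(from = lv, to = lv))
  visits <- rowSums(counts)
  tm <- counts
  occupied <- visits > 0
  tm[occupied, ] <- tm[occupied, , drop = FALSE] / visits[occupied]
  list(matrix = tm, visitCounts = visits, unvisited = !occupied)
}

.transitionFeatureNames <- function(k) {
  g <- expand.grid(to = seq_len(k), from = seq_len(k))[, 2:1]
  sprintf("P(%d->%d)", g$from, g$to)
}

#' Flatten a transition matrix to named features
#'
#' Row-major `[from, to]` flattening with names `P(j->i)`; K = 5 gives the 25
#' transition features. `unflattenTransitions()` is the exact inverse.
#'
#' @param tm a k x k transition matrix (or the list from
#'   [transitionMatrix()]).
#' @param v named or plain K^2 vector in row-major `[from, to]` order.
#' @return `flattenTransitions`: named numeric vector of length K^2;
#'   `unflattenTransitions`: the K x K matrix.
#' @export
flattenTransitions <- function(tm) {
  if (is.list(tm)) tm <- tm$matrix
  stopifnot(is.matrix(tm), nrow(tm) == ncol(tm))
  stats::setNames(as.vector(t(tm)), .transitionFeatureNames(nrow(tm)))
}

#' @rdname flattenTransitions
#' @export
unflattenTransitions <- function(v) {
  k <- sqrt(length(v))
  if (k != round(k)) stop("length is not K^2 for any integer K")
  t(matrix(as.numeric(v), k, k))
}

#' Occupancy and mean dwell time of a state sequence
#'
#' Fractional occupancy (fraction of windows spent in each state; sums to 1)
#' and mean dwell time (average length of consecutive runs, in windows;
#' 0 and flagged for states never visited).
#'
#' @param seq integer state sequence (values in 1..k).
#' @param k number of states.
#' @return list with `occupancy`, `meanDwell` (K-vectors) and `unvisited`
#'   flags.
#' @export
occupancyDwell <- function(seq, k) {
  seq <- as.integer(seq)
  if (length(seq) < 1L) stop("state sequence must be nonempty")
  if (any(seq < 1L | seq > k)) stop("state values must lie in 1..", k)
  occ <- as.vector(table(factor(seq, levels = seq_len(k)))) / length(seq)
  r <- rle(seq)
  dwell <- vapply(seq_len(k), function(j) {
    runs <- r$lengths[r$values == j]
    if (length(runs)) mean(runs) else 0
  }, numeric(1))
  list(occupancy = occ, meanDwell = dwell, unvisited = occ == 0)
}

#' Transition features for every subject of a state model
#'
#' Applies [transitionMatrix()] to each subject's state sequence and collects
#' the flattened K^2 features into a subjects x K^2 matrix. Features
#' originating from a flagged (never-occupied) state are set to NA so that
#' downstream correlations drop them pairwise.
#'
#' @param model a [StateModel-class].
#' @return a [TransitionSet-class].
#' @examples
#' cohort <- generateCohort(defaultCohortConfig(nHC = 3, nSZ = 3, targetR = 0,
#'                                              seed = 2))
#' model <- clusterStates(computeDFC(cohort), k = 5, nReplicates = 5)
#' transitionFeatures(model)
#' @export
transitionFeatures <- function(model) {
  stopifnot(is(model, "StateModel"))
  K <- model@nStates
  tms <- lapply(model@assignments, transitionMatrix, k = K)
  fm <- t(vapply(tms, function(tm) {
    v <- flattenTransitions(tm$matrix)
    v[rep(tm$unvisited, each = K)] <- NA_real_
    v
  }, numeric(K * K)))
  rownames(fm) <- names(model@assignments)
  new("TransitionSet",
      matrices = lapply(tms, `[[`, "matrix"),
      visitCounts = lapply(tms, `[[`, "visitCounts"),
      featureMatrix = fm, nStates = K)
}
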