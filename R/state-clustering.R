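# Row-standardize so that tcrossprod gives Pearson correlations across
# features. Rows with zero variance are the caller's problem (checked).
.rowStandardize <- function(X) {
  xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(xc^2))
  bad <- nrm < 1e-12
  nrm[bad] <- 1
  list(R = xc / nrm, degenerate = bad)
}

#' Correlation-distance k-means over windowed connectivity
#'
#' Lloyd's algorithm with distance `d(x, c) = 1 - Pearson(x, c)` and
#' arithmetic-mean centroid updates (not renormalized), k-means++-style
#' seeding, best of `nReplicates` restarts by total within-cluster distance.
#' Convergence is declared when assignments stop changing. A cluster left
#' empty after reassignment is re-seeded from the window farthest from its
#' assigned centroid. Deterministic given `seed`.
#'
#' @param X pooled windows x features matrix; no row may have zero variance
#'   across features.
#' @param k number of clusters (k = 1 returns the pooled mean).
#' @param nReplicates random restarts (default 50).
#' @param maxIter maximum Lloyd iterations per replicate (default 1000).
#' @param seed integer seed.
#' @return list with `centroids` (k x P), `assignment` (length-n integer),
#'   `totWithin`, `iterations`, `objectiveTrace` (within-cluster distance
#'   after each assignment step of the winning replicate).
#' @export
kmeansCorrelation <- function(X, k, nReplicates = 50L, maxIter = 1000L,
                              seed = 1L) {
  stopifnot(is.matrix(X), k >= 1, nrow(X) >= k)
  rs <- .rowStandardize(X)
  if (any(rs$degenerate))
    stop("window(s) ", paste(utils::head(which(rs$degenerate), 5), collapse = ", "),
         " have zero variance across features; drop or jitter them before ",
         "clustering with correlation distance")
  n <- nrow(X)
  if (k == 1L)
    return(list(centroids = matrix(colMeans(X), 1, ncol(X),
                                   dimnames = list(NULL, colnames(X))),
                assignment = rep(1L, n),
                totWithin = sum(1 - tcrossprod(rs$R,
                  .rowStandardize(matrix(colMeans(X), 1))$R)),
                iterations = 0L))
  set.seed(seed)
  best <- NULL
  for (rep in seq_len(nReplicates)) {
    fit <- .lloydCorr(X, rs$R, k, maxIter)
    if (is.null(best) || fit$totWithin < best$totWithin) best <- fit
  }
  colnames(best$centroids) <- colnames(X)
  best
}

# One k-means++-seeded Lloyd run under correlation distance.
.lloydCorr <- function(X, R, k, maxIter) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- (1 - tcrossprod(R, R[centers[1], , drop = FALSE]))[, 1]^2
  for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1L, prob = p)
    dj <- (1 - tcrossprod(R, R[centers[j], , drop = FALSE]))[, 1]
    d2 <- pmin(d2, dj^2)
  }
  C <- X[centers, , drop = FALSE]
  assign_prev <- integer(n)
  iter <- 0L
  objective <- numeric()
  repeat {
    iter <- iter + 1L
    Cn <- .rowStandardize(C)$R
    sim <- tcrossprod(R, Cn)
    assign_cur <- max.col(sim, ties.method = "first")
    dvec <- 1 - sim[cbind(seq_len(n), assign_cur)]
    # re-seed empty clusters from the farthest window
    empty <- setdiff(seq_len(k), unique(assign_cur))
    for (j in empty) {
      far <- which.max(dvec)
      assign_cur[far] <- j
      dvec[far] <- 0
    }
    objective[iter] <- sum(dvec)
    if (identical(assign_cur, assign_prev) || iter > maxIter) break
    assign_prev <- assign_cur
    C <- rowsum(X, assign_cur) / as.vector(table(factor(assign_cur, levels = seq_len(k))))
  }
  Cn <- .rowStandardize(C)$R
  sim <- tcrossprod(R, Cn)
  list(centroids = C, assignment = assign_cur,
       totWithin = sum(1 - sim[cbind(seq_len(n), assign_cur)]),
       iterations = iter, objectiveTrace = objective)
}

# Pool a DFCSet (or pass a matrix through) and remember per-subject spans.
.poolWindows <- function(x) {
  if (is.matrix(x))
    return(list(X = x, spans = list(pooled = seq_len(nrow(x)))))
  stopifnot(is(x, "DFCSet"))
  Ts <- vapply(x@features, nrow, integer(1))
  ends <- cumsum(Ts)
  starts <- ends - Ts + 1L
  list(X = do.call(rbind, x@features),
       spans = stats::setNames(Map(seq.int, starts, ends), names(x@features)))
}

#' Select the number of states by the elbow criterion
#'
#' For each candidate k, clusters the pooled windows and computes the ratio
#' `R(k)` of mean within-cluster distance to mean between-centroid distance
#' (both under `1 - Pearson`). The selected K maximizes the discrete second
#' difference `R(k-1) - 2 R(k) + R(k+1)` over the interior of the range (the
#' knee); ties go to the smallest k. The knee strength — the maximal second
#' difference divided by the total drop of the curve — is reported so that a
#' weak elbow (no real cluster structure) is visible; values below 0.15 are
#' flagged. Ranges shorter than 3 cannot support the knee rule: the smallest
#' candidate is returned with a warning.
#'
#' @param x a [DFCSet-class] or a pooled windows x features matrix.
#' @param kRange candidate k values (default 2:10).
#' @param nReplicates,maxIter,seed passed to [kmeansCorrelation()].
#' @return list with `k` (selected), `curve` (data.frame k, ratio),
#'   `kneeStrength`, `lowKnee` flag.
#' @export
selectKElbow <- function(x, kRange = 2:10, nReplicates = 50L, maxIter = 1000L,
                         seed = 1L) {
  kRange <- sort(unique(as.integer(kRange)))
  if (!length(kRange)) stop("kRange must be nonempty")
  if (any(kRange < 2L)) stop("kRange must contain values >= 2")
  pooled <- .poolWindows(x)
  if (max(kRange) >= nrow(pooled$X)) stop("each k must be below the number of windows")
  ratio <- vapply(seq_along(kRange), function(i) {
    fit <- kmeansCorrelation(pooled$X, kRange[i], nReplicates, maxIter,
                             seed = seed + i)
    within <- fit$totWithin / nrow(pooled$X)
    Cn <- .rowStandardize(fit$centroids)$R
    sims <- tcrossprod(Cn)
    between <- mean(1 - sims[upper.tri(sims)])
    within / between
  }, numeric(1))
  curve <- data.frame(k = kRange, ratio = ratio)
  if (length(kRange) < 3L) {
    warning("kRange shorter than 3: knee rule unavailable, returning the ",
            "smallest candidate k = ", kRange[1])
    return(list(k = kRange[1], curve = curve, kneeStrength = NA_real_,
                lowKnee = NA))
  }
  d2 <- ratio[-c(length(ratio), length(ratio) - 1)] -
    2 * ratio[-c(1, length(ratio))] + ratio[-c(1, 2)]
  kneeAt <- which.max(d2)                      # ties -> smallest k
  drop_total <- max(ratio) - min(ratio)
  strength <- if (drop_total > 0) max(d2) / drop_total else 0
  list(k = kRange[kneeAt + 1L], curve = curve, kneeStrength = strength,
       lowKnee = strength < 0.15)
}

#' Cluster windowed connectivity into recurring states
#'
#' Pools the windows of all subjects (both groups together), runs
#' correlation-distance k-means ([kmeansCorrelation()]), and splits the pooled
#' assignment back into per-subject state sequences. When `k = "auto"` the
#' number of states is first chosen by [selectKElbow()] over `kRange`.
#'
#' @param dfc a [DFCSet-class] (or pooled matrix; assignments are then
#'   returned as a single pooled sequence).
#' @param k number of states, or `"auto"` for elbow selection.
#' @param kRange candidate range for `k = "auto"`.
#' @param nReplicates,maxIter,seed passed to [kmeansCorrelation()].
#' @return a [StateModel-class].
#' @export
clusterStates <- function(dfc, k = "auto", kRange = 2:10, nReplicates = 50L,
                          maxIter = 1000L, seed = 1L) {
  pooled <- .poolWindows(dfc)
  curve <- data.frame(k = integer(), ratio = numeric())
  knee <- NA_real_
  if (identical(k, "auto")) {
    sel <- selectKElbow(dfc, kRange = kRange, nReplicates = nReplicates,
                        maxIter = maxIter, seed = seed)
    k <- sel$k
    curve <- sel$curve
    knee <- sel$kneeStrength
  }
  k <- as.integer(k)
  fit <- kmeansCorrelation(pooled$X, k, nReplicates, maxIter, seed = seed)
  new("StateModel",
      nStates = k, centroids = fit$centroids,
      assignments = lapply(pooled$spans, function(s) fit$assignment[s]),
      inertiaCurve = curve, kneeStrength = knee,
      distance = "correlation", totWithin = fit$totWithin,
      seed = as.integer(seed))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
  dimnames(out) <- NULL
  out
}

#' Match states between two centroid sets
#'
#' Computes all pairwise Pearson correlations between the rows of two centroid
#' matrices and the one-to-one assignment maximizing total correlation (exact
#' enumeration up to 8 states, greedy beyond). With unequal state counts the
#' smaller set is matched greedily and extras are left unmatched. The full
#' similarity matrix is returned alongside the permutation so weak matches
#' remain visible.
#'
#' @param centroidsA,centroidsB K x P centroid matrices (equal P).
#' @return list with `permutation` (for each row of A, the matched row of B,
#'   NA if unmatched), `matchedCorrelations`, `similarity` (Ka x Kb matrix).
#' @export
matchStates <- function(centroidsA, centroidsB) {
  stopifnot(is.matrix(centroidsA), is.matrix(centroidsB),
            ncol(centroidsA) == ncol(centroidsB))
  sim <- stats::cor(t(centroidsA), t(centroidsB))
  ka <- nrow(centroidsA); kb <- nrow(centroidsB)
  perm <- rep(NA_integer_, ka)
  if (ka == kb && ka <= 8L) {
    perms <- .permutations(ka)
    scores <- vapply(seq_len(nrow(perms)), function(r)
      sum(sim[cbind(seq_len(ka), perms[r, ])]), numeric(1))
    perm <- perms[which.max(scores), ]
  } else {
    avail <- seq_len(kb)
    for (i in order(apply(sim, 1, max), decreasing = TRUE)) {
      if (!length(avail)) break
      j <- avail[which.max(sim[i, avail])]
      perm[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  list(permutation = perm,
       matchedCorrelations = ifelse(is.na(perm), NA_real_,
                                    sim[cbind(seq_len(ka), perm)]),
       similarity = sim)
}

#' Per-state block-mean connectivity summary
#'
#' Averages each state centroid within and between anatomical node groups
#' (e.g. PCu, ACC, PCC): for G groups, the G within-block means (over distinct
#' node pairs inside a group) and the G(G-1)/2 between-block means — the
#' six-column summary for three groups.
#'
#' @param model a [StateModel-class].
#' @param nodeGroups named list assigning every node to exactly one group.
#' @param nodeNames node labels in feature order (column order of the signals
#'   the model was fitted on).
#' @return data.frame, one row per state, one column per block.
#' @export
stateSummary <- function(model, nodeGroups, nodeNames) {
  stopifnot(is(model, "StateModel"))
  missing <- setdiff(nodeNames, unlist(nodeGroups))
  if (length(missing))
    stop("node(s) absent from the group map: ", paste(missing, collapse = ", "))
  gnames <- names(nodeGroups)
  blocks <- c(gnames,
              utils::combn(gnames, 2, paste, collapse = "/"))
  out <- matrix(NA_real_, model@nStates, length(blocks),
                dimnames = list(paste0("state", seq_len(model@nStates)), blocks))
  for (k in seq_len(model@nStates)) {
    M <- devectorizeFC(model@centroids[k, ], nodeNames)
    for (g in gnames) {
      ii <- match(nodeGroups[[g]], nodeNames)
      out[k, g] <- if (length(ii) > 1)
        mean(M[ii, ii][upper.tri(M[ii, ii])]) else NA_real_
    }
    cc <- utils::combn(gnames, 2)
    for (p in seq_len(ncol(cc))) {
      ii <- match(nodeGroups[[cc[1, p]]], nodeNames)
      jj <- match(nodeGroups[[cc[2, p]]], nodeNames)
      out[k, paste(cc[1, p], cc[2, p], sep = "/")] <- mean(M[ii, jj])
    }
  }
  as.data.frame(out)
}
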