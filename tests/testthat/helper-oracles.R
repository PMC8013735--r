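# Independent brute-force oracles used across test files. These deliberately
# use naive loops, not the package's vectorized code paths.

# Taper by direct convolution summation: rectangle of L+1 ones, Gaussian
# kernel on +/- 4 sigma samples, central L+1 crop, unit sum.
oracleTaper <- function(L, sigma, tr) {
  s <- sigma / tr
  m <- max(1, ceiling(4 * s))
  kx <- -m:m
  kern <- exp(-kx^2 / (2 * s^2))
  kern <- kern / sum(kern)
  rect <- rep(1, L + 1)
  nf <- L + 1 + 2 * m
  full <- numeric(nf)
  for (i in seq_len(nf)) {
    acc <- 0
    for (j in seq_len(L + 1)) {
      ki <- i - j + 1
      if (ki >= 1 && ki <= 2 * m + 1) acc <- acc + rect[j] * kern[ki]
    }
    full[i] <- acc
  }
  w <- full[(m + 1):(m + 1 + L)]
  w / sum(w)
}

# Weighted covariance of one segment by explicit double loop (reliability
# weights, unbiased).
oracleWeightedCov <- function(seg, w) {
  C <- ncol(seg)
  mu <- numeric(C)
  for (j in seq_len(C)) mu[j] <- sum(w * seg[, j])
  S <- matrix(0, C, C)
  for (a in seq_len(C)) for (b in seq_len(C)) {
    acc <- 0
    for (t in seq_len(nrow(seg)))
      acc <- acc + w[t] * (seg[t, a] - mu[a]) * (seg[t, b] - mu[b])
    S[a, b] <- acc / (1 - sum(w^2))
  }
  S
}

# Row-wise upper-triangle vectorization by explicit loop.
oracleVectorize <- function(M) {
  out <- c()
  for (i in seq_len(nrow(M) - 1))
    for (j in (i + 1):ncol(M)) out <- c(out, M[i, j])
  out
}

# Transition counts by explicit enumeration.
oracleTransitionCounts <- function(s, k) {
  N <- matrix(0, k, k)
  for (t in seq_len(length(s) - 1)) N[s[t], s[t + 1]] <- N[s[t], s[t + 1]] + 1
  N
}

# Mean run length per state by explicit run enumeration.
oracleMeanDwell <- function(s, k) {
  runs <- list()
  start <- 1
  for (t in seq_along(s)) {
    if (t == length(s) || s[t + 1] != s[t]) {
      runs[[length(runs) + 1]] <- c(state = s[start], len = t - start + 1)
      start <- t + 1
    }
  }
  sapply(seq_len(k), function(j) {
    lens <- sapply(runs, function(r) if (r["state"] == j) r["len"] else NA)
    lens <- lens[!is.na(lens)]
    if (length(lens)) mean(lens) else 0
  })
}

# Partial correlation by explicit normal-equations residualization.
oraclePartialCor <- function(x, y, Z) {
  D <- cbind(1, Z)
  bx <- solve(t(D) %*% D, t(D) %*% x)
  by <- solve(t(D) %*% D, t(D) %*% y)
  rx <- x - D %*% bx
  ry <- y - D %*% by
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

# BH step-up q-values straight from the definition.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) m * p[o[j]] / j)
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# Per-block centroid means by explicit averaging.
oracleBlockMeans <- function(M, groups, nodeNames) {
  gn <- names(groups)
  out <- c()
  for (g in gn) {
    ii <- match(groups[[g]], nodeNames)
    vals <- c()
    if (length(ii) > 1)
      for (a in seq_along(ii)) for (b in seq_along(ii))
        if (a < b) vals <- c(vals, M[ii[a], ii[b]])
    out[g] <- if (length(vals)) mean(vals) else NA
  }
  for (p1 in seq_along(gn)) for (p2 in seq_along(gn)) if (p1 < p2) {
    ii <- match(groups[[gn[p1]]], nodeNames)
    jj <- match(groups[[gn[p2]]], nodeNames)
    vals <- c()
    for (a in ii) for (b in jj) vals <- c(vals, M[a, b])
    out[paste(gn[p1], gn[p2], sep = "/")] <- mean(vals)
  }
  out
}

# Small well-separated two-group fixture in feature space (not via the
# generator) for clustering tests.
plantedClusters <- function(n = 60, P = 21, noise = 0.05, seed = 1) {
  set.seed(seed)
  c1 <- rep(c(1, -1), length.out = P)
  c2 <- -c1
  lab <- rep(1:2, each = n / 2)
  X <- t(sapply(lab, function(l) (if (l == 1) c1 else c2) + rnorm(P, 0, noise)))
  list(X = X, labels = lab, centroids = rbind(c1, c2))
}
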