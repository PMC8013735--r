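#' Covariate-adjusted partial Pearson correlation
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares and correlates the residuals. The two-sided p-value uses
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of freedom,
#' with `k` covariate columns. Rows with any missing value are dropped
#' pairwise. With no covariates this is the plain Pearson correlation. When a
#' residual is (numerically) constant — e.g. `y` an exact linear function of
#' a covariate — the correlation is undefined and reported as NA with a
#' degeneracy note.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric design matrix (no intercept column;
#'   categorical covariates must already be indicator-coded, see
#'   [associateTransitions()]).
#' @return list: `r`, `p`, `n` (rows used), `df`, `degenerate`.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  n0 <- length(x)
  if (length(y) != n0 || (!is.null(covariates) && nrow(covariates) != n0))
    stop("x, y and covariates must have equal length")
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) keep <- keep & apply(is.finite(covariates), 1, all)
  x <- x[keep]; y <- y[keep]
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- length(x)
  if (n <= k + 2L)
    stop("need more than k + 2 = ", k + 2L, " complete observations, got ", n)
  design <- cbind(intercept = rep(1, n),
                  if (!is.null(covariates)) covariates[keep, , drop = FALSE])
  rx <- stats::residuals(stats::lm.fit(design, x))
  ry <- stats::residuals(stats::lm.fit(design, y))
  if (stats::sd(rx) < 1e-12 * max(1, stats::sd(x)) ||
      stats::sd(ry) < 1e-12 * max(1, stats::sd(y)))
    return(list(r = NA_real_, p = NA_real_, n = n, df = n - 2L - k,
                degenerate = TRUE))
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), n = n, df = df,
       degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values `q_(i) = min_{j >= i} m p_(j) / j`, returned in the input
#' order (a thin validating wrapper over `p.adjust(method = "BH")`).
#'
#' @param pvals p-values in `[0, 1]`; NAs pass through.
#' @return q-values of equal length.
#' @export
bhFDR <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# Indicator-code a covariate data.frame; constant columns (e.g. a single
# acquisition site) are dropped rather than breaking the design.
.covariateDesign <- function(df) {
  if (is.null(df) || ncol(df) == 0) return(NULL)
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      out <- matrix(v, dimnames = list(NULL, nm))
    } else {
      v <- factor(v)
      if (nlevels(droplevels(v)) < 2L) return(NULL)
      out <- stats::model.matrix(~ v)[, -1, drop = FALSE]
      colnames(out) <- paste0(nm, levels(v)[-1])
    }
    s <- stats::sd(out[, 1])
    if (ncol(out) == 1 && (is.na(s) || s == 0)) return(NULL)
    out
  })
  cols <- Filter(Negate(is.null), cols)
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

#' Associate transition features with symptom scores
#'
#' For each symptom scale, computes the covariate-adjusted partial Pearson
#' correlation between every transition feature and the scale over the SZ
#' subjects with a non-missing score, then adjusts the per-scale family of
#' K^2 p-values by Benjamini-Hochberg FDR. Missing scores and flagged
#' (unvisited-state) features are dropped pairwise; features with too few
#' complete observations are skipped with NA. Scales with no scores at all
#' are skipped with a warning.
#'
#' @param tset a [TransitionSet-class] (or its feature matrix) covering the
#'   cohort's subjects.
#' @param cohort the [TimeCourseSet-class] with symptom scores and
#'   covariates.
#' @param scales symptom scale column names (default the three PANSS scales).
#' @param covariates covariate column names to adjust for (default age and
#'   gender; add `"site"` for multi-site cohorts). Categorical covariates are
#'   indicator-coded; covariates constant across the used subjects are
#'   dropped.
#' @return data.frame (association report): `scale`, `feature`, `r`, `n`,
#'   `p`, `q`, sorted by q within scale.
#' @export
associateTransitions <- function(tset, cohort,
                                 scales = c("panss_positive", "panss_negative",
                                            "panss_total"),
                                 covariates = c("age", "gender")) {
  fm <- if (is(tset, "TransitionSet")) featureMatrix(tset) else as.matrix(tset)
  info <- as.data.frame(subjectInfo(cohort))
  sz <- info[info$group == "SZ", , drop = FALSE]
  fm <- fm[match(sz$id, rownames(fm)), , drop = FALSE]
  out <- list()
  for (sc in scales) {
    score <- sz[[sc]]
    if (all(is.na(score))) {
      warning("scale ", sc, " has no scores; skipped")
      next
    }
    res <- lapply(colnames(fm), function(f) {
      x <- fm[, f]
      keep <- is.finite(x) & is.finite(score)
      cov <- .covariateDesign(sz[keep, covariates, drop = FALSE])
      pc <- tryCatch(
        partialCorrelation(x[keep], score[keep], cov),
        error = function(e) list(r = NA_real_, p = NA_real_, n = sum(keep)))
      data.frame(scale = sc, feature = f, r = pc$r, n = pc$n, p = pc$p)
    })
    tab <- do.call(rbind, res)
    tab$q <- bhFDR(tab$p)
    out[[sc]] <- tab[order(tab$q, tab$p), ]
  }
  if (!length(out)) stop("no usable symptom scale")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
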