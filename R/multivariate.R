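.FEATURE_COLS <- c("total_eods", "n_runs", "mode_ipi_ms",
                   "range_high_ms", "range_low_ms")

.checkFeatureTable <- function(table, minRows = 3L) {
  if (!is.data.frame(table)) stop("feature table must be a data.frame")
  miss <- setdiff(.FEATURE_COLS, names(table))
  if (length(miss)) {
    stop("feature table is missing columns: ", paste(miss, collapse = ", "))
  }
  X <- as.matrix(table[, .FEATURE_COLS])
  if (nrow(X) < minRows) stop("need at least ", minRows, " rows")
  if (anyNA(X)) stop("feature table has missing cells")
  if (any(X <= 0)) {
    stop("all features must be strictly positive (log-transformable)")
  }
  X
}

#' PCA of an SPI feature table
#'
#' Log10-transforms the five features, centres and scales them to unit
#' variance, and decomposes by singular value decomposition
#' (\code{prcomp}). Because SVD signs are arbitrary, each component is
#' oriented so its largest-magnitude loading is positive, making scores and
#' loadings reproducible. The log base is immaterial after standardisation
#' and is fixed at 10 for reproducibility.
#'
#' @param table data.frame with the five feature columns (see
#'   [featureTable()]) plus any id columns; >= 3 rows, all features > 0.
#' @return List with \code{scores} (rows x components), \code{loadings}
#'   (features x components, unit-norm columns), \code{explained_fraction}
#'   (summing to 1), and \code{row_info} (the non-feature columns of the
#'   input, for grouping).
#' @examples
#' cohort <- simulateCohortTrains(4, seed = 1)
#' pcaFeatures(featureTable(cohort))$explained_fraction
#' @export
pcaFeatures <- function(table) {
  X <- .checkFeatureTable(table, minRows = 3L)
  L <- log10(X)
  const <- apply(L, 2L, function(col) diff(range(col)) == 0)
  if (any(const)) {
    stop("constant feature(s) after log transform: ",
         paste(colnames(L)[const], collapse = ", "))
  }
  p <- stats::prcomp(L, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(p$rotation, 2L, flip, `*`)
  scores <- sweep(p$x, 2L, flip, `*`)
  ev <- p$sdev^2
  list(scores = scores, loadings = rot,
       explained_fraction = ev / sum(ev),
       row_info = table[, setdiff(names(table), .FEATURE_COLS),
                        drop = FALSE])
}

#' Pairwise Pearson correlations of the feature table
#'
#' Pearson r for every pair of the five (log-untransformed) features, with
#' two-sided p-values from the t distribution. Constant features yield NA
#' correlations, reported as such.
#'
#' @param table feature data.frame, >= 3 rows.
#' @return List with matrices \code{r} (unit diagonal) and \code{p}
#'   (NA diagonal), and \code{n} rows used.
#' @export
pearsonMatrix <- function(table) {
  X <- .checkFeatureTable(table, minRows = 3L)
  n <- nrow(X)
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

#' Two-group and k-group comparisons of a feature
#'
#' Thin wrappers over the standard routines: Welch two-sample t-test or
#' Kruskal-Wallis rank-sum test, with the effect direction (difference of
#' group means, first minus second level) reported for the two-group case.
#'
#' @param values numeric vector.
#' @param groups factor or character of group labels.
#' @param test \code{"two_sample_t"} (exactly 2 groups) or
#'   \code{"kruskal_wallis"} (>= 2 groups).
#' @return List with \code{statistic}, \code{p_value}, \code{test}, group
#'   \code{means}, and for the t-test \code{direction} (sign of mean
#'   difference).
#' @export
compareGroups <- function(values, groups,
                          test = c("two_sample_t", "kruskal_wallis")) {
  test <- match.arg(test)
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  m <- tapply(values, groups, mean)
  means <- stats::setNames(as.numeric(m), names(m))
  if (test == "two_sample_t") {
    if (nlevels(groups) != 2L) stop("two_sample_t requires exactly 2 groups")
    tt <- stats::t.test(values ~ groups)
    list(test = test, statistic = unname(tt$statistic),
         p_value = tt$p.value, means = means,
         direction = sign(means[1] - means[2]))
  } else {
    if (nlevels(groups) < 2L) stop("kruskal_wallis requires >= 2 groups")
    kw <- stats::kruskal.test(values, groups)
    list(test = test, statistic = unname(kw$statistic),
         p_value = kw$p.value, means = means)
  }
}
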