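# Multivariate summaries: PCA on scaled/centered data with
# variance-explained reporting, hierarchical clustering with correlation
# distance and average linkage, and row z-scoring for heatmaps.
#
# Matrices are features x samples (the proteomics convention); rows with any
# missing value are dropped before PCA/clustering (complete-case).

.drop_incomplete_rows <- function(mat, what) {
  bad <- rowSums(is.na(mat)) > 0
  if (any(bad)) {
    warn_("%s: dropping %d row(s) with missing values", what, sum(bad))
    mat <- mat[!bad, , drop = FALSE]
  }
  mat
}

#' Principal component analysis of samples
#'
#' PCA on the transposed (samples x features) matrix with features centered
#' and scaled across samples. Reports scores, loadings and the fraction of
#' variance explained by every component (summing to 1, nonincreasing).
#' Component signs follow a deterministic convention: the largest-magnitude
#' loading of each component is positive. Constant features cannot be
#' scaled and are dropped with a warning.
#'
#' @param mat numeric matrix, features x samples
#' @param center,scale. passed to the underlying decomposition
#' @return list with `scores` (samples x PC), `loadings` (features x PC)
#'   and `variance_explained`
#' @export
pca_scores <- function(mat, center = TRUE, scale. = TRUE) {
  stopifnot(is.matrix(mat))
  mat <- .drop_incomplete_rows(mat, "pca_scores")
  if (ncol(mat) < 2L || nrow(mat) < 2L) {
    abort_("PCA needs >= 2 samples and >= 2 complete features")
  }
  if (scale.) {
    sds <- apply(mat, 1L, stats::sd)
    const <- sds == 0 | is.na(sds)
    if (any(const)) {
      warn_("pca_scores: dropping %d constant feature(s) (cannot scale)", sum(const))
      mat <- mat[!const, , drop = FALSE]
      if (nrow(mat) < 2L) abort_("fewer than 2 non-constant features")
    }
  }
  pc <- stats::prcomp(t(mat), center = center, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation, variance_explained = ve)
}

#' Hierarchical clustering with correlation distance, average linkage
#'
#' Agglomerative clustering of rows with distance `1 - Pearson correlation`
#' and average linkage. Zero-variance rows have undefined correlation and
#' are dropped with a warning.
#'
#' @param mat numeric matrix (rows are clustered)
#' @return an `hclust` object (merge tree, heights, leaf order)
#' @export
hcluster <- function(mat) {
  stopifnot(is.matrix(mat))
  mat <- .drop_incomplete_rows(mat, "hcluster")
  sds <- apply(mat, 1L, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warn_("hcluster: dropping %d zero-variance row(s) (correlation undefined)",
          sum(const))
    mat <- mat[!const, , drop = FALSE]
  }
  if (nrow(mat) < 2L) abort_("clustering needs >= 2 usable rows")
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  stats::hclust(d, method = "average")
}

#' Row z-scores
#'
#' Centers and scales each row to mean 0 and sample (n-1) standard
#' deviation 1 across samples; missing cells stay missing and are excluded
#' from the row moments. Constant rows become all zero, with a warning.
#'
#' @param mat numeric matrix
#' @return matrix of the same shape
#' @export
zscore_rows <- function(mat) {
  stopifnot(is.matrix(mat))
  mu <- rowMeans(mat, na.rm = TRUE)
  sds <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const)) warn_("zscore_rows: %d constant row(s) set to zero", sum(const))
  sds[const] <- 1  # constant rows: x - mean is already 0 everywhere observed
  sweep(sweep(mat, 1L, mu, "-"), 1L, sds, "/")
}
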