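## Per-layer preprocessing: variance-based feature selection, min-max
## normalization to [0,1], and correlation-driven feature reordering so
## that convolution windows slide over mutually correlated features.

.defaultFeatureCounts <- c(rna = 3000L, mirna = 100L, methylation = 1000L)

#' Keep the most variable features of a layer
#'
#' Retains the `n` features with the largest sample variance, ordered by
#' descending variance with ties broken by original feature order.  When
#' `n` is `NULL` the per-modality defaults are used: 3000 for RNA, 100 for
#' miRNA, 1000 for methylation; other layer kinds keep all features.  If a
#' layer holds fewer than `n` features, all are kept with a warning.
#'
#' @param layer an [OmicsLayer-class] with no missing entries.
#' @param n positive integer, number of features to keep, or `NULL` for the
#'   per-modality default.
#' @return An [OmicsLayer-class] with at most `n` features.
#' @export
selectTopVariance <- function(layer, n = NULL) {
  stopifnot(is(layer, "OmicsLayer"))
  m <- as.matrix(layer)
  if (!ncol(m)) stop("empty matrix")
  if (is.null(n)) {
    n <- .defaultFeatureCounts[layerKind(layer)]
    if (is.na(n)) n <- ncol(m)
  }
  n <- as.integer(n)
  stopifnot(n >= 1L)
  v <- apply(m, 2L, var)
  if (n > ncol(m)) {
    warning(sprintf("requested %d features but only %d available; keeping all",
                    n, ncol(m)))
    n <- ncol(m)
  }
  ## order() is stable, so ties fall back to original feature order
  ord <- order(-v)[seq_len(n)]
  OmicsLayer(m[, ord, drop = FALSE], layerKind(layer))
}

#' Min-max normalization per feature
#'
#' Linearly rescales each feature to `[0, 1]` via
#' `x' = (x - x_min) / (x_max - x_min)`.  Constant features (where the
#' denominator vanishes) map to 0 and are flagged degenerate in the record;
#' they carry no information and are normally removed upstream by the
#' variance filter.
#'
#' @param layer an [OmicsLayer-class] with no missing entries.
#' @return list with `layer` (normalized [OmicsLayer-class]) and `record`,
#'   a data.frame with per-feature `feature`, `xmin`, `xmax`, `degenerate`
#'   usable by [minMaxDenormalize()].
#' @export
minMaxNormalize <- function(layer) {
  stopifnot(is(layer, "OmicsLayer"))
  m <- as.matrix(layer)
  if (any(!is.finite(m))) stop("missing entries: apply dropMissing() first")
  xmin <- apply(m, 2L, min)
  xmax <- apply(m, 2L, max)
  rng <- xmax - xmin
  deg <- rng == 0
  rngSafe <- ifelse(deg, 1, rng)
  out <- sweep(sweep(m, 2L, xmin, "-"), 2L, rngSafe, "/")
  out[, deg] <- 0
  list(layer = OmicsLayer(out, layerKind(layer)),
       record = data.frame(feature = colnames(m), xmin = xmin, xmax = xmax,
                           degenerate = deg, row.names = NULL,
                           stringsAsFactors = FALSE))
}

#' Undo min-max normalization
#'
#' @param layer normalized [OmicsLayer-class].
#' @param record the `record` returned by [minMaxNormalize()].
#' @return An [OmicsLayer-class] on the original scale (degenerate features
#'   are restored to their constant value).
#' @export
minMaxDenormalize <- function(layer, record) {
  m <- as.matrix(layer)
  stopifnot(identical(colnames(m), record$feature))
  rng <- ifelse(record$degenerate, 0, record$xmax - record$xmin)
  out <- sweep(sweep(m, 2L, rng, "*"), 2L, record$xmin, "+")
  OmicsLayer(out, layerKind(layer))
}

#' Geometric-mean correlation score per feature
#'
#' For feature i, the score is the geometric mean of the absolute Pearson
#' correlations of its row of the feature correlation matrix,
#' `rho_i = (prod_j |corr(i, j)|)^(1/n)`, the self-correlation (|1|)
#' included as a neutral term.  Zero-variance features get `rho = 0`.
#' @noRd
.geomMeanCorrelation <- function(m) {
  n <- ncol(m)
  sds <- apply(m, 2L, sd)
  ok <- sds > 0
  rho <- numeric(n)
  if (any(ok)) {
    cm <- abs(cor(m[, ok, drop = FALSE]))
    ## geometric mean via log-sum; an exactly-zero correlation => rho = 0
    lg <- suppressWarnings(log(cm))
    g <- ifelse(apply(cm == 0, 1L, any), 0, exp(rowMeans(lg)))
    rho[ok] <- g
  }
  rho
}

#' Reorder features by correlation connectedness
#'
#' Scores every feature by the geometric mean of the absolute Pearson
#' correlations in its row of the feature-feature correlation matrix and
#' sorts features by that score in descending order (most mutually
#' correlated first), ties broken by original index; zero-variance features
#' are placed last with score 0.  The returned record allows the
#' permutation to be inverted.
#'
#' @param layer a normalized [OmicsLayer-class] with at least two samples.
#' @return list with `layer` (reordered), and `record` holding
#'   `permutation` (new position -> original index) and `rho`
#'   (per-original-feature score).
#' @export
correlationReorder <- function(layer) {
  stopifnot(is(layer, "OmicsLayer"))
  m <- as.matrix(layer)
  if (nrow(m) < 2L)
    stop("correlation undefined for a single-sample matrix")
  rho <- .geomMeanCorrelation(m)
  perm <- order(-rho)           # stable: ties keep original order
  list(layer = OmicsLayer(m[, perm, drop = FALSE], layerKind(layer)),
       record = list(permutation = perm,
                     rho = setNames(rho, colnames(m))))
}

#' Preprocess one omics layer for encoding
#'
#' Convenience chain: variance selection, min-max normalization, and
#' (optionally) correlation reordering, in that order.
#'
#' @param layer an [OmicsLayer-class] (complete; see [dropMissing()]).
#' @param nFeatures passed to [selectTopVariance()].
#' @param reorder logical, apply [correlationReorder()]?
#' @return list with `layer` plus the `normRecord` and `reorderRecord`.
#' @export
preprocessLayer <- function(layer, nFeatures = NULL, reorder = TRUE) {
  sel <- selectTopVariance(layer, nFeatures)
  nrm <- minMaxNormalize(sel)
  if (reorder) {
    ro <- correlationReorder(nrm$layer)
    list(layer = ro$layer, normRecord = nrm$record,
         reorderRecord = ro$record)
  } else {
    list(layer = nrm$layer, normRecord = nrm$record, reorderRecord = NULL)
  }
}
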