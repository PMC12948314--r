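#' @import methods
#' @useDynLib omicsCAE, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var cor sd quantile rnorm runif rexp pchisq pnorm
#'   prcomp p.adjust predict uniroot setNames coef median dist
#' @importFrom utils head tail read.delim write.table
NULL

#' OmicsLayer: one omics modality as a samples x features matrix
#'
#' Container for a single omics layer (e.g. RNA-seq expression, miRNA-seq
#' expression, DNA methylation beta values) in canonical samples x features
#' orientation.  Row names are sample identifiers, column names are feature
#' identifiers; both must be unique.
#'
#' @slot values numeric matrix, samples in rows, features in columns,
#'   with unique dimnames.
#' @slot layerKind character scalar, one of `"rna"`, `"mirna"`,
#'   `"methylation"`, `"proteomic"`, `"other"`.
#'
#' @seealso [readOmicsMatrix()], [dropMissing()], [alignCohort()]
#' @export
setClass("OmicsLayer",
  representation(values = "matrix", layerKind = "character"))

.layerKinds <- c("rna", "mirna", "methylation", "proteomic", "other")

setValidity("OmicsLayer", function(object) {
  v <- object@values
  msgs <- character()
  if (length(object@layerKind) != 1L || !object@layerKind %in% .layerKinds)
    msgs <- c(msgs, sprintf("layerKind must be one of %s",
                            paste(.layerKinds, collapse = ", ")))
  if (!is.numeric(v))
    msgs <- c(msgs, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must carry sample (row) and feature (column) names")
  else {
    if (anyDuplicated(rownames(v)))
      msgs <- c(msgs, "duplicate sample IDs")
    if (anyDuplicated(colnames(v)))
      msgs <- c(msgs, "duplicate feature IDs")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OmicsLayer
#'
#' @param values numeric matrix, samples x features, with dimnames.
#' @param layerKind one of `"rna"`, `"mirna"`, `"methylation"`,
#'   `"proteomic"`, `"other"`.
#' @return An [OmicsLayer-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' OmicsLayer(m, "rna")
#' @export
OmicsLayer <- function(values, layerKind = "other") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("OmicsLayer", values = values, layerKind = layerKind)
}

#' MultiOmicsCohort: aligned multi-omics layers plus survival follow-up
#'
#' Holds one or more [OmicsLayer-class] objects sharing an identical sample
#' order, a survival table (columns `sample`, `time`, `event`) and an
#' optional clinical covariate table.  Construct with [alignCohort()], which
#' intersects samples and canonicalizes their order.
#'
#' @slot layers named list of [OmicsLayer-class] objects, identical sample
#'   order across layers.
#' @slot survival data.frame with columns `sample`, `time` (days, >= 0) and
#'   `event` (1 = death observed, 0 = censored), same sample order as the
#'   layers.
#' @slot clinical data.frame of categorical covariates keyed by `sample`
#'   (may have zero columns beyond `sample` when absent).
#' @export
setClass("MultiOmicsCohort",
  representation(layers = "list", survival = "data.frame",
                 clinical = "data.frame"))

setValidity("MultiOmicsCohort", function(object) {
  msgs <- character()
  if (!length(object@layers))
    msgs <- c(msgs, "at least one omics layer is required")
  if (!all(vapply(object@layers, is, TRUE, class2 = "OmicsLayer")))
    msgs <- c(msgs, "layers must all be OmicsLayer objects")
  else {
    ids <- lapply(object@layers, function(l) rownames(l@values))
    if (length(unique(ids)) != 1L)
      msgs <- c(msgs, "all layers must share one sample order")
    s <- object@survival
    if (!all(c("sample", "time", "event") %in% names(s)))
      msgs <- c(msgs, "survival needs columns sample, time, event")
    else {
      if (!identical(as.character(s$sample), ids[[1]]))
        msgs <- c(msgs, "survival sample order must match the layers")
      if (any(!is.finite(s$time)) || any(s$time < 0))
        msgs <- c(msgs, "survival time must be finite and >= 0")
      if (!all(s$event %in% c(0, 1)))
        msgs <- c(msgs, "event must be 0 (censored) or 1 (death)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' TrainedCAE: a fitted convolutional autoencoder for one omics layer
#'
#' Returned by [trainCAE()].  Carries the learned parameters, the per-epoch
#' reconstruction-loss history, the training configuration and a fingerprint
#' of the input feature order; [encodeSamples()] refuses matrices whose
#' feature order does not match the fingerprint.
#'
#' @slot params list of weight/bias arrays for every layer of the network.
#' @slot lossHistory numeric vector of per-epoch mean squared
#'   reconstruction errors.
#' @slot config the [caeConfig()] list used for training.
#' @slot featureFingerprint character vector of feature IDs in the order
#'   the encoder expects.
#' @export
setClass("TrainedCAE",
  representation(params = "list", lossHistory = "numeric",
                 config = "list", featureFingerprint = "character"))

setValidity("TrainedCAE", function(object) {
  if (!length(object@lossHistory)) "empty loss history" else TRUE
})

#' SubtypeCall: a K-means subtype assignment with diagnostics
#'
#' @slot labels integer cluster label per sample, `1..k`, canonicalized by
#'   descending cluster size; named by sample ID when available.
#' @slot k integer number of clusters.
#' @slot objective the K-means objective J (total within-cluster sum of
#'   squared Euclidean distances to the centroids).
#' @slot centers numeric matrix of cluster centroids (k x features).
#' @slot diagnostics data.frame of per-k diagnostics (silhouette, log-rank
#'   p, CH, DB, BIC) when produced by [selectNumClusters()]; zero rows
#'   otherwise.
#' @slot seed integer seed used.
#' @export
setClass("SubtypeCall",
  representation(labels = "integer", k = "integer", objective = "numeric",
                 centers = "matrix", diagnostics = "data.frame",
                 seed = "integer"))

setValidity("SubtypeCall", function(object) {
  msgs <- character()
  if (object@objective < 0) msgs <- c(msgs, "objective J must be >= 0")
  tab <- tabulate(object@labels, nbins = object@k)
  if (any(tab == 0L)) msgs <- c(msgs, "every cluster must be non-empty")
  if (length(msgs)) msgs else TRUE
})
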