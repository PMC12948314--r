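#' Sample identifiers
#'
#' @param x an [OmicsLayer-class] or [MultiOmicsCohort-class].
#' @return Character vector of sample IDs in canonical order.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Feature identifiers of an omics layer
#'
#' @param x an [OmicsLayer-class].
#' @return Character vector of feature IDs.
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' Omics layer kind
#'
#' @param x an [OmicsLayer-class].
#' @return One of `"rna"`, `"mirna"`, `"methylation"`, `"proteomic"`,
#'   `"other"`.
#' @export
setGeneric("layerKind", function(x) standardGeneric("layerKind"))

#' Omics layers of a cohort
#'
#' @param x a [MultiOmicsCohort-class].
#' @return Named list of [OmicsLayer-class] objects.
#' @export
setGeneric("cohortLayers", function(x) standardGeneric("cohortLayers"))

#' Survival table of a cohort
#'
#' @param x a [MultiOmicsCohort-class].
#' @return data.frame with columns `sample`, `time`, `event`.
#' @export
setGeneric("survivalData", function(x) standardGeneric("survivalData"))

#' Clinical covariate table of a cohort
#'
#' @param x a [MultiOmicsCohort-class].
#' @return data.frame keyed by `sample`; zero covariate columns when no
#'   clinical table was supplied.
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' Cluster labels of a subtype assignment
#'
#' @param x a [SubtypeCall-class].
#' @return Integer vector of labels `1..k`, named by sample where known.
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' Per-epoch training loss
#'
#' @param x a [TrainedCAE-class].
#' @return Numeric vector of per-epoch mean squared reconstruction errors.
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' Encode samples into the latent space
#'
#' @param model a [TrainedCAE-class].
#' @param x an [OmicsLayer-class] or numeric matrix whose feature order
#'   matches the model's fingerprint.
#' @return Numeric matrix, samples x latent dimensions.
#' @export
setGeneric("encodeSamples", function(model, x) standardGeneric("encodeSamples"))

#' @describeIn OmicsLayer-class sample IDs
#' @param x object
#' @export
setMethod("sampleIDs", "OmicsLayer", function(x) rownames(x@values))

#' @describeIn OmicsLayer-class feature IDs
#' @export
setMethod("featureIDs", "OmicsLayer", function(x) colnames(x@values))

#' @describeIn OmicsLayer-class layer kind
#' @export
setMethod("layerKind", "OmicsLayer", function(x) x@layerKind)

#' @describeIn OmicsLayer-class underlying samples x features matrix
#' @export
setMethod("as.matrix", "OmicsLayer", function(x, ...) x@values)

#' @describeIn OmicsLayer-class number of samples
#' @export
setMethod("nrow", "OmicsLayer", function(x) nrow(x@values))

#' @describeIn OmicsLayer-class number of features
#' @export
setMethod("ncol", "OmicsLayer", function(x) ncol(x@values))

setMethod("show", "OmicsLayer", function(object) {
  cat(sprintf("OmicsLayer [%s]: %d samples x %d features\n",
              object@layerKind, nrow(object@values), ncol(object@values)))
})

#' @describeIn MultiOmicsCohort-class sample IDs (shared by all layers)
#' @export
setMethod("sampleIDs", "MultiOmicsCohort",
          function(x) rownames(x@layers[[1]]@values))

#' @describeIn MultiOmicsCohort-class list of layers
#' @export
setMethod("cohortLayers", "MultiOmicsCohort", function(x) x@layers)

#' @describeIn MultiOmicsCohort-class survival table
#' @export
setMethod("survivalData", "MultiOmicsCohort", function(x) x@survival)

#' @describeIn MultiOmicsCohort-class clinical table
#' @export
setMethod("clinicalData", "MultiOmicsCohort", function(x) x@clinical)

setMethod("show", "MultiOmicsCohort", function(object) {
  cat(sprintf("MultiOmicsCohort: %d samples, %d layer(s)\n",
              length(sampleIDs(object)), length(object@layers)))
  for (nm in names(object@layers)) {
    l <- object@layers[[nm]]
    cat(sprintf("  %-12s [%s] %d features\n", nm, l@layerKind,
                ncol(l@values)))
  }
  ev <- object@survival$event
  cat(sprintf("  survival: %d events, %d censored\n", sum(ev == 1),
              sum(ev == 0)))
  nc <- setdiff(names(object@clinical), "sample")
  if (length(nc))
    cat(sprintf("  clinical: %s\n", paste(nc, collapse = ", ")))
})

#' @describeIn TrainedCAE-class per-epoch loss history
#' @param x object
#' @export
setMethod("lossHistory", "TrainedCAE", function(x) x@lossHistory)

setMethod("show", "TrainedCAE", function(object) {
  cfg <- object@config
  cat(sprintf(
    "TrainedCAE (%s): %d input features -> %d latent, %d epochs, final MSE %.4g\n",
    cfg$variant, length(object@featureFingerprint), cfg$latentDim,
    length(object@lossHistory), tail(object@lossHistory, 1L)))
})

#' @describeIn SubtypeCall-class cluster labels
#' @param x object
#' @export
setMethod("subtypeLabels", "SubtypeCall", function(x) x@labels)

setMethod("show", "SubtypeCall", function(object) {
  cat(sprintf("SubtypeCall: k = %d, n = %d, J = %.4g\n",
              object@k, length(object@labels), object@objective))
  print(table(cluster = object@labels))
  if (nrow(object@diagnostics)) {
    cat("per-k diagnostics:\n")
    print(object@diagnostics, row.names = FALSE)
  }
})
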