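## Orchestration: preprocess each layer, encode (CAE / PCA / NMF), filter
## latent features by survival association (unless ablated), cluster with
## data-driven k, and evaluate (log-rank, concordance + bootstrap CI, SVM
## pseudo-label validation, clinical associations, agreement vs an
## optional reference labeling).

#' Pipeline configuration
#'
#' @param featureCounts named vector of variance-filter sizes per layer
#'   (`NULL` entries use the per-modality defaults of
#'   [selectTopVariance()]).
#' @param reorder apply [correlationReorder()] before encoding.
#' @param reducer `"cae"`, `"pca"` or `"nmf"`.
#' @param variant `"full"`, `"no_attention"` (attention block replaced by
#'   the identity) or `"no_cox"` (survival feature filtering skipped;
#'   all latent features are clustered).
#' @param latentDim latent features per layer (clamped per layer to below
#'   half the encoded feature count).
#' @param epochs,batchSize,learningRate,weightDecay,r CAE training
#'   settings, see [caeConfig()].
#' @param alpha univariate Cox significance threshold.
#' @param cvFolds folds for the LASSO penalty search and the SVM grid.
#' @param kRange candidate subtype numbers.
#' @param nInit K-means restarts.
#' @param nBoot bootstrap replicates for the concordance CI.
#' @param classifier run the SVM pseudo-label validation.
#' @param nPerLayer classifier features per layer.
#' @param seed master seed; every stage derives its own stream from it.
#' @return A named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(featureCounts = NULL, reorder = TRUE,
                           reducer = c("cae", "pca", "nmf"),
                           variant = c("full", "no_attention", "no_cox"),
                           latentDim = 100L, epochs = 100L,
                           batchSize = 16L, learningRate = 1e-3,
                           weightDecay = 3, r = 8L,
                           alpha = 0.05, cvFolds = 5L, kRange = 2:5,
                           nInit = 10L, nBoot = 1000L, classifier = TRUE,
                           nPerLayer = 50L, seed = 1L) {
  reducer <- match.arg(reducer)
  variant <- match.arg(variant)
  structure(list(featureCounts = featureCounts, reorder = reorder,
                 reducer = reducer, variant = variant,
                 latentDim = as.integer(latentDim),
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, weightDecay = weightDecay,
                 r = as.integer(r),
                 alpha = alpha, cvFolds = as.integer(cvFolds),
                 kRange = kRange, nInit = as.integer(nInit),
                 nBoot = as.integer(nBoot), classifier = classifier,
                 nPerLayer = as.integer(nPerLayer),
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

.layerSeed <- function(seed, i)
  as.integer((as.numeric(seed) * 131 + as.numeric(i) * 7919) %% 2147483647)

#' Run the full subtyping pipeline on an aligned cohort
#'
#' Stages, in order: per-layer variance filter, min-max normalization and
#' correlation reordering; per-layer encoding by the attention CAE (or a
#' PCA/NMF baseline); per-layer LASSO + univariate-Cox latent-feature
#' filtering (skipped for `variant = "no_cox"`); column concatenation;
#' K-means with silhouette-gated, log-rank-driven selection of k; and
#' evaluation (log-rank across subtypes, Cox linear-predictor concordance
#' with a percentile bootstrap CI, SVM pseudo-label validation, clinical
#' chi-square associations with FDR, and ARI/NMI against
#' `referenceLabels` when given).  Deterministic for a fixed config seed.
#'
#' @param cohort a [MultiOmicsCohort-class] from [alignCohort()] or
#'   [generateCohort()].
#' @param config a [pipelineConfig()].
#' @param referenceLabels optional labeling (e.g. ground truth or another
#'   method's subtypes) to score agreement against.
#' @return An `EvaluationReport` list: `subtypes` (a
#'   [SubtypeCall-class]), `k`, `perK` diagnostics, `logrank`, `cindex`,
#'   `cindexCI`, `classifier`, `associations`, `agreement`,
#'   `selectedFeatures`, `lossHistories`, `provenance`.
#' @export
runPipeline <- function(cohort, config = pipelineConfig(),
                        referenceLabels = NULL) {
  stopifnot(is(cohort, "MultiOmicsCohort"),
            inherits(config, "pipelineConfig"))
  surv <- survivalData(cohort)
  layers <- cohortLayers(cohort)
  latents <- list()
  lossHistories <- list()
  for (i in seq_along(layers)) {
    nm <- names(layers)[i]
    nf <- if (!is.null(config$featureCounts)) config$featureCounts[[nm]]
          else NULL
    prep <- preprocessLayer(layers[[i]], nFeatures = nf,
                            reorder = config$reorder)
    X <- prep$layer
    p <- ncol(as.matrix(X))
    ld <- min(config$latentDim, max(2L, p %/% 2L))
    lseed <- .layerSeed(config$seed, i)
    if (config$reducer == "cae") {
      cfg <- caeConfig(latentDim = ld, epochs = config$epochs,
                       batchSize = min(config$batchSize, nrow(as.matrix(X))),
                       learningRate = config$learningRate,
                       weightDecay = config$weightDecay, r = config$r,
                       seed = lseed,
                       variant = if (config$variant == "no_attention")
                         "no_attention" else "full")
      model <- trainCAE(X, cfg)
      lossHistories[[nm]] <- lossHistory(model)
      lat <- encodeSamples(model, X)
    } else {
      lat <- baselineReduce(X, method = config$reducer, nComponents = ld,
                            seed = lseed)
    }
    latents[[nm]] <- lat
  }
  if (config$variant == "no_cox") {
    selected <- combineSelected(lapply(latents, function(l)
      list(latent = l, selected = colnames(l))))
    selection <- NULL
  } else {
    selection <- list()
    perLayer <- list()
    for (nm in names(latents)) {
      lat <- latents[[nm]]
      ls <- lassoSelect(lat, surv, cvFolds = config$cvFolds,
                        seed = .layerSeed(config$seed, match(nm,
                                                             names(latents))
                                          + 100L))
      filt <- coxUnivariateFilter(lat, ls$features, surv,
                                  alpha = config$alpha)
      selection[[nm]] <- filt
      perLayer[[nm]] <- list(latent = lat, selected = filt)
    }
    selected <- combineSelected(perLayer)
  }
  call <- selectNumClusters(selected, surv, kRange = config$kRange,
                            seed = config$seed, nInit = config$nInit)
  labels <- subtypeLabels(call)
  logrank <- logrankTest(surv, labels)
  risk <- riskScoreForCindex(selected, surv)
  cidx <- concordanceIndex(risk, surv, mode = "harrell")
  ci <- bootstrapCI(function(idx) {
    concordanceIndex(risk[idx], surv[idx, , drop = FALSE])$cindex
  }, nSamples = nrow(surv), nBoot = config$nBoot, seed = config$seed)
  classifier <- NULL
  if (config$classifier) {
    Z <- buildClassifierMatrix(cohort, config$nPerLayer)
    classifier <- tryCatch(
      trainValidateSVM(Z, labels, survival = surv,
                       cvFolds = config$cvFolds, seed = config$seed),
      error = function(e) {
        warning("classifier validation skipped: ", conditionMessage(e))
        NULL
      })
  }
  associations <- NULL
  clin <- clinicalData(cohort)
  covars <- setdiff(names(clin), "sample")
  if (length(covars)) {
    res <- lapply(covars, function(cv)
      tryCatch(chiSquareAssociation(labels, clin[[cv]], name = cv),
               error = function(e) NULL))
    res <- Filter(Negate(is.null), res)
    if (length(res)) {
      associations <- data.frame(
        variable = vapply(res, `[[`, "", "name"),
        chisq = vapply(res, `[[`, 0, "chisq"),
        df = vapply(res, `[[`, 0L, "df"),
        p = vapply(res, `[[`, 0, "p"),
        cramersV = vapply(res, `[[`, 0, "cramersV"))
      associations$fdr <- fdrAdjust(associations$p)
      associations$significant <- associations$fdr < 0.05
    }
  }
  agreement <- NULL
  if (!is.null(referenceLabels))
    agreement <- clusteringAgreement(labels, referenceLabels)
  report <- list(subtypes = call, k = call@k, perK = call@diagnostics,
                 logrank = logrank, cindex = cidx$cindex,
                 cindexCI = c(lower = ci$lower, upper = ci$upper),
                 classifier = classifier, associations = associations,
                 agreement = agreement,
                 selectedFeatures = colnames(selected),
                 selection = selection, lossHistories = lossHistories,
                 provenance = list(configHash = rlang::hash(config),
                                   seed = config$seed,
                                   variant = config$variant,
                                   reducer = config$reducer,
                                   nSamples = nrow(surv),
                                   timestamp = format(Sys.time())))
  class(report) <- "EvaluationReport"
  report
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport (%s, reducer %s, seed %d)\n",
              x$provenance$variant, x$provenance$reducer,
              x$provenance$seed))
  cat(sprintf("  n = %d, chosen k = %d\n", x$provenance$nSamples, x$k))
  cat(sprintf("  log-rank: %s = %.3f, df = %d, p = %.3g\n",
              if (x$logrank$df == 1L) "Z" else "chi-square",
              x$logrank$statistic, x$logrank$df, x$logrank$p))
  cat(sprintf("  C-index = %.3f (95%% CI %.3f-%.3f)\n", x$cindex,
              x$cindexCI["lower"], x$cindexCI["upper"]))
  if (!is.null(x$classifier))
    cat(sprintf("  SVM test accuracy = %.3f\n", x$classifier$accuracy))
  if (!is.null(x$agreement))
    cat(sprintf("  agreement vs reference: ARI = %.3f, NMI = %.3f\n",
                x$agreement$ari, x$agreement$nmi))
  invisible(x)
}

#' Standard synthetic benchmark configuration
#'
#' One seeded instance of the package's standard benchmark: the default
#' [simulationConfig()] cohort (n = 300, 3 subtypes, hazard ratios 1:2:4,
#' strong effects) and a matching desk-scale [pipelineConfig()] (20
#' epochs, 32 latent features per layer, batch 32, 200 bootstrap
#' replicates).  Used throughout the test suite and the acceptance
#' script so every benchmark result refers to the same conditions.
#'
#' @param seed integer seed applied to both the generator and the
#'   pipeline.
#' @param ... overrides forwarded to [pipelineConfig()].
#' @return list with `simConfig` and `pipeConfig`.
#' @export
standardBenchmark <- function(seed = 1L, ...) {
  list(simConfig = simulationConfig(seed = seed),
       pipeConfig = pipelineConfig(
         featureCounts = c(rna = 300L, methylation = 200L, mirna = 100L),
         epochs = 20L, latentDim = 32L, batchSize = 32L, nBoot = 200L,
         seed = seed, ...))
}

#' Compare pipeline variants or reducers on one cohort
#'
#' Runs [runPipeline()] once per requested variant/reducer with a shared
#' seed and tabulates the headline numbers.
#'
#' @param cohort a [MultiOmicsCohort-class].
#' @param baseConfig a [pipelineConfig()] supplying shared settings.
#' @param variants character vector drawn from `"full"`,
#'   `"no_attention"`, `"no_cox"` (pipeline variants) and/or `"pca"`,
#'   `"nmf"` (reducer swaps).
#' @param referenceLabels optional reference labeling for ARI/NMI.
#' @return data.frame with one row per variant: `variant`, `k`,
#'   `silhouette`, `logrankP`, `cindex`, and `ari` when a reference is
#'   given.
#' @export
compareVariants <- function(cohort, baseConfig = pipelineConfig(),
                            variants = c("full", "no_attention", "no_cox"),
                            referenceLabels = NULL) {
  stopifnot(length(variants) >= 2L)
  rows <- lapply(variants, function(v) {
    cfg <- baseConfig
    if (v %in% c("pca", "nmf")) { cfg$reducer <- v; cfg$variant <- "full" }
    else cfg$variant <- v
    rep <- runPipeline(cohort, cfg, referenceLabels = referenceLabels)
    sil <- rep$perK$silhouette[rep$perK$k == rep$k]
    data.frame(variant = v, k = rep$k, silhouette = sil,
               logrankP = rep$logrank$p, cindex = rep$cindex,
               ari = if (is.null(rep$agreement)) NA_real_
                     else rep$agreement$ari)
  })
  do.call(rbind, rows)
}
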