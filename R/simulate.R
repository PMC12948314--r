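## Seeded generator of multi-omics survival cohorts with planted subtype
## structure: block-correlated informative features carrying
## subtype-specific mean shifts, exponential (or Weibull) subtype-specific
## hazards, and independent uniform censoring tuned to a target rate.

#' Configuration for the synthetic multi-omics cohort generator
#'
#' Defaults describe the package's standard synthetic benchmark: 300
#' samples, 3 equally likely subtypes, three layers (rna 300, methylation
#' 200, mirna 100 features with 60/40/20 informative features), strong
#' mean-shift effects (size 2 in noise-s.d. units), within-block
#' correlation 0.5, unit noise, exponential hazards in ratio 1:2:4 and a
#' 30% censoring target.
#'
#' @param nSamples cohort size.
#' @param nSubtypes number of planted subtypes.
#' @param mixtureProps subtype mixture proportions (sum to 1).
#' @param featureCounts named integer vector, features per layer; names
#'   become layer names and kinds (`rna`, `methylation`, `mirna`, ...).
#' @param informativeCounts named integer vector, informative features per
#'   layer (must not exceed `featureCounts`).
#' @param effectSize standard deviation of the per-(block, subtype) mean
#'   shifts, in noise-s.d. units.
#' @param rhoBlock within-block noise correlation in `[0, 1)`.
#' @param blockSize informative features per correlated block.
#' @param noiseSd residual noise standard deviation.
#' @param hazards positive per-subtype exponential rates (per day); with
#'   `weibullShape != 1` they act as Weibull rate parameters.
#' @param weibullShape Weibull shape (1 = exponential).
#' @param censoringRate target fraction censored, in `[0, 0.95]`.
#' @param seed integer seed.
#' @return A named list of class `simulationConfig`.
#' @export
simulationConfig <- function(nSamples = 300L, nSubtypes = 3L,
                             mixtureProps = NULL,
                             featureCounts = c(rna = 300L,
                                               methylation = 200L,
                                               mirna = 100L),
                             informativeCounts = c(rna = 60L,
                                                   methylation = 40L,
                                                   mirna = 20L),
                             effectSize = 2, rhoBlock = 0.5,
                             blockSize = 10L, noiseSd = 1,
                             hazards = c(0.001, 0.002, 0.004),
                             weibullShape = 1, censoringRate = 0.3,
                             seed = 1L) {
  if (is.null(mixtureProps)) mixtureProps <- rep(1 / nSubtypes, nSubtypes)
  stopifnot(length(mixtureProps) == nSubtypes,
            abs(sum(mixtureProps) - 1) < 1e-8,
            length(hazards) == nSubtypes, all(hazards > 0),
            rhoBlock >= 0, rhoBlock < 1,
            identical(names(featureCounts), names(informativeCounts)),
            all(informativeCounts <= featureCounts))
  if (censoringRate > 0.95)
    stop("censoring target above 0.95 is infeasible")
  structure(list(nSamples = as.integer(nSamples),
                 nSubtypes = as.integer(nSubtypes),
                 mixtureProps = mixtureProps,
                 featureCounts = featureCounts,
                 informativeCounts = informativeCounts,
                 effectSize = effectSize, rhoBlock = rhoBlock,
                 blockSize = as.integer(blockSize), noiseSd = noiseSd,
                 hazards = hazards, weibullShape = weibullShape,
                 censoringRate = censoringRate, seed = as.integer(seed)),
            class = "simulationConfig")
}

.layerKindFromName <- function(nm) {
  if (nm %in% .layerKinds) nm else "other"
}

#' Generate a synthetic multi-omics survival cohort
#'
#' Subtype labels are drawn from the mixture proportions.  Within each
#' layer, informative features are organised in blocks of `blockSize`;
#' every (block, subtype) pair receives a mean shift drawn from
#' `N(0, effectSize^2)`, and noise within a block shares a common factor
#' giving pairwise correlation `rhoBlock`.  Non-informative features are
#' independent `N(0, noiseSd^2)`.  Methylation-kind layers are squashed to
#' `[0, 1]` by the logistic function to respect the beta-value scale.
#' Survival times are exponential (or Weibull) with the subtype's hazard;
#' censoring is independent `Uniform(0, cMax)` with `cMax` tuned so the
#' expected censoring fraction matches the target.  Everything is
#' reproducible from the seed.
#'
#' @param config a [simulationConfig()].
#' @return list with `cohort` (a [MultiOmicsCohort-class]) and `truth`
#'   (list: `subtype` per sample, `informativeFeatures` per layer,
#'   `hazards`, `riskScore` = log hazard per sample, `cMax`).
#' @export
generateCohort <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(config$seed)
  n <- config$nSamples
  ids <- sprintf("S%04d", seq_len(n))
  subtype <- sample.int(config$nSubtypes, n, replace = TRUE,
                        prob = config$mixtureProps)
  layers <- list()
  informative <- list()
  for (nm in names(config$featureCounts)) {
    p <- config$featureCounts[[nm]]
    pi <- config$informativeCounts[[nm]]
    M <- matrix(rnorm(n * p, sd = config$noiseSd), n, p)
    if (pi > 0) {
      blocks <- split(seq_len(pi),
                      ceiling(seq_len(pi) / config$blockSize))
      for (blk in blocks) {
        shifts <- rnorm(config$nSubtypes, sd = config$effectSize)
        shared <- rnorm(n)
        rho <- config$rhoBlock
        for (f in blk) {
          eps <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)
          M[, f] <- shifts[subtype] + config$noiseSd * eps
        }
      }
    }
    if (.layerKindFromName(nm) == "methylation") M <- .sigmoid(M)
    dimnames(M) <- list(ids, sprintf("%s_f%04d", nm, seq_len(p)))
    layers[[nm]] <- OmicsLayer(M, .layerKindFromName(nm))
    informative[[nm]] <- colnames(M)[seq_len(pi)]
  }
  lambda <- config$hazards[subtype]
  shape <- config$weibullShape
  tTrue <- if (shape == 1) rexp(n, rate = lambda)
           else (-log(runif(n)))^(1 / shape) / lambda
  if (config$censoringRate > 0) {
    ## E[censored | cMax] = mean(min(t / cMax, 1)) for C ~ U(0, cMax)
    target <- config$censoringRate
    f <- function(cm) mean(pmin(tTrue / cm, 1)) - target
    hi <- max(tTrue) / max(target, 1e-3) * 2
    cMax <- uniroot(f, c(min(tTrue[tTrue > 0]) * 1e-6, hi))$root
    cens <- runif(n, 0, cMax)
  } else {
    cMax <- Inf
    cens <- rep(Inf, n)
  }
  event <- as.integer(tTrue <= cens)
  time <- pmin(tTrue, cens)
  surv <- data.frame(sample = ids, time = time, event = event,
                     stringsAsFactors = FALSE)
  cohort <- alignCohort(layers, surv)
  ord <- match(sampleIDs(cohort), ids)
  truth <- list(subtype = setNames(subtype[ord], ids[ord]),
                informativeFeatures = informative,
                hazards = config$hazards,
                riskScore = setNames(log(lambda)[ord], ids[ord]),
                cMax = cMax)
  list(cohort = cohort, truth = truth)
}

#' Write a synthetic cohort to delimited text
#'
#' Emits the same TSV formats [readOmicsMatrix()] and
#' [readSurvivalTable()] read (features-as-rows matrices, a survival
#' table), plus a `truth.tsv` with the planted subtype per sample.
#'
#' @param sim the list returned by [generateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohortLayers(sim$cohort)))
    writeOmicsMatrix(cohortLayers(sim$cohort)[[nm]],
                     file.path(dir, paste0(nm, ".tsv")))
  write.table(survivalData(sim$cohort), file.path(dir, "survival.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(sim$truth$subtype),
                         subtype = sim$truth$subtype),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
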