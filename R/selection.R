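## Two-stage survival-association filter on latent features: (1) L1
## penalized Cox partial likelihood (glmnet) keeps features with non-zero
## coefficients at the cross-validated penalty; (2) a univariate Cox model
## per surviving feature keeps those with coefficient p < alpha.  Selected
## features from all omics layers are then column-concatenated.

#' @importFrom glmnet glmnet cv.glmnet
#' @importFrom survival Surv coxph coxph.control survdiff concordance
NULL

.asSurv <- function(survival) {
  stopifnot(all(c("time", "event") %in% names(survival)))
  survival::Surv(survival$time, survival$event)
}

#' LASSO (L1 Cox) latent-feature selection
#'
#' Fits an L1-penalized Cox partial-likelihood path and picks the penalty
#' by cross-validated partial likelihood; features with non-zero
#' coefficients at that penalty are returned.  Survival times equal to 0
#' are nudged to half the smallest positive time (the Cox partial
#' likelihood requires positive times).
#'
#' @param latent samples x latent-features matrix (rows aligned with
#'   `survival`).
#' @param survival data.frame with `time` and `event` columns.
#' @param nPenalties number of log-spaced penalties on the path.
#' @param cvFolds number of cross-validation folds.
#' @param seed seed controlling fold assignment.
#' @return list with `features` (character IDs, possibly empty) and
#'   `coefficients` (named numeric vector at the chosen penalty).
#' @export
lassoSelect <- function(latent, survival, nPenalties = 50L, cvFolds = 5L,
                        seed = 1L) {
  latent <- as.matrix(latent)
  stopifnot(nrow(latent) == nrow(survival))
  if (nrow(latent) < 2L * cvFolds)
    stop("need at least 2 * cvFolds samples")
  if (sum(survival$event) == 0)
    stop("no events: the Cox partial likelihood is undefined")
  tt <- survival$time
  if (any(tt <= 0)) tt[tt <= 0] <- min(tt[tt > 0]) / 2
  y <- survival::Surv(tt, survival$event)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(cvFolds), nrow(latent)))
  cv <- glmnet::cv.glmnet(latent, y, family = "cox", alpha = 1,
                          nlambda = nPenalties, foldid = folds,
                          standardize = TRUE)
  beta <- as.numeric(coef(cv, s = "lambda.min"))
  names(beta) <- colnames(latent)
  keep <- beta != 0
  if (!any(keep))
    warning("all LASSO coefficients are zero at every penalty; ",
            "no feature selected")
  list(features = names(beta)[keep], coefficients = beta[keep])
}

#' Univariate Cox screening of candidate features
#'
#' For each candidate latent feature, fits a single-covariate Cox
#' proportional-hazards model and retains features whose coefficient test
#' p-value is below `alpha` (no multiple-testing correction by default;
#' pass the result through [fdrAdjust()] if desired).  The alternative
#' `method = "logrank_median"` dichotomizes each feature at its median and
#' uses the two-group log-rank test instead.  Features whose fit fails to
#' converge are dropped with a warning, never a hard error.
#'
#' @param latent samples x latent-features matrix.
#' @param features candidate feature IDs (columns of `latent`), e.g. from
#'   [lassoSelect()].
#' @param survival data.frame with `time` and `event`.
#' @param alpha significance threshold (default 0.05).
#' @param method `"cox"` (Wald test on the Cox coefficient, default) or
#'   `"logrank_median"` (median-split log-rank).
#' @return data.frame with columns `feature`, `coef`, `hazardRatio`, `p`,
#'   `retained`; attribute `alpha` records the threshold.
#' @export
coxUnivariateFilter <- function(latent, features, survival, alpha = 0.05,
                                method = c("cox", "logrank_median")) {
  method <- match.arg(method)
  latent <- as.matrix(latent)
  if (!all(features %in% colnames(latent)))
    stop("candidate features missing from the latent matrix")
  y <- .asSurv(survival)
  rows <- lapply(features, function(f) {
    x <- latent[, f]
    if (method == "cox") {
      fit <- tryCatch(
        survival::coxph(y ~ x,
                        control = survival::coxph.control(iter.max = 50)),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit) || !is.finite(coef(fit)[1L])) {
        warning("dropping feature '", f, "': Cox fit did not converge")
        return(NULL)
      }
      s <- summary(fit)$coefficients
      data.frame(feature = f, coef = s[1L, "coef"],
                 hazardRatio = s[1L, "exp(coef)"],
                 p = s[1L, "Pr(>|z|)"], stringsAsFactors = FALSE)
    } else {
      grp <- as.integer(x > stats::median(x))
      if (length(unique(grp)) < 2L) {
        warning("dropping feature '", f, "': median split is degenerate")
        return(NULL)
      }
      lr <- logrankTest(survival, grp)
      data.frame(feature = f, coef = NA_real_, hazardRatio = NA_real_,
                 p = lr$p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(feature = character(), coef = numeric(),
                      hazardRatio = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  out$retained <- out$p < alpha
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Combine survival-selected features across omics layers
#'
#' Column-concatenates the retained latent features of each layer in layer
#' order (original feature order within a layer), prefixing feature IDs
#' with the layer name so IDs stay unique.
#'
#' @param perLayer named list; each element a list with `latent` (matrix)
#'   and `selected` (the data.frame from [coxUnivariateFilter()], or a
#'   character vector of feature IDs).
#' @return samples x total-retained-features matrix.
#' @export
combineSelected <- function(perLayer) {
  stopifnot(length(perLayer) >= 1L)
  nms <- names(perLayer)
  if (is.null(nms)) nms <- paste0("layer", seq_along(perLayer))
  blocks <- list()
  for (i in seq_along(perLayer)) {
    el <- perLayer[[i]]
    lat <- as.matrix(el$latent)
    sel <- el$selected
    feats <- if (is.character(sel)) sel else sel$feature[sel$retained]
    feats <- intersect(colnames(lat), feats)  # original order, deterministic
    if (!length(feats)) next
    b <- lat[, feats, drop = FALSE]
    colnames(b) <- paste(nms[i], feats, sep = ".")
    blocks[[length(blocks) + 1L]] <- b
  }
  if (!length(blocks))
    stop("no features survived survival selection in any layer; ",
         "consider relaxing alpha")
  out <- do.call(cbind, blocks)
  rownames(out) <- rownames(as.matrix(perLayer[[1L]]$latent))
  out
}
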