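## Downstream validation: SVM pseudo-label classifier on top-variance
## features, chi-square clinical association with Cramer's V and FDR
## control, and ARI/NMI agreement between clusterings.

#' Build the classifier feature matrix
#'
#' Per omics layer: min-max normalize, keep the `nPerLayer` most variable
#' features, and column-concatenate across layers (layer-prefixed IDs).
#' Layers with fewer than `nPerLayer` features contribute all of them with
#' a warning.
#'
#' @param cohort a [MultiOmicsCohort-class].
#' @param nPerLayer features kept per layer (default 50).
#' @return samples x (<= nPerLayer * layers) matrix.
#' @export
buildClassifierMatrix <- function(cohort, nPerLayer = 50L) {
  layers <- cohortLayers(cohort)
  blocks <- lapply(names(layers), function(nm) {
    l <- layers[[nm]]
    if (!ncol(as.matrix(l))) stop("layer '", nm, "' is empty")
    nrm <- minMaxNormalize(l)$layer
    sel <- selectTopVariance(nrm, min(nPerLayer, ncol(as.matrix(nrm))))
    if (ncol(as.matrix(nrm)) < nPerLayer)
      warning(sprintf("layer '%s' has only %d features (< %d); keeping all",
                      nm, ncol(as.matrix(nrm)), nPerLayer))
    b <- as.matrix(sel)
    colnames(b) <- paste(nm, colnames(b), sep = ".")
    b
  })
  do.call(cbind, blocks)
}

.stratifiedSplit <- function(labels, trainFrac) {
  train <- integer(0)
  for (g in unique(labels)) {
    idx <- which(labels == g)
    nTrain <- max(1L, round(trainFrac * length(idx)))
    train <- c(train, sample(idx, min(nTrain, length(idx))))
  }
  sort(train)
}

.stratifiedFolds <- function(labels, nFolds) {
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

#' Default SVM hyperparameter grid
#'
#' Linear and RBF kernels, `C` in 0.1/1/10/100; for the RBF kernel,
#' `gamma` in `1/p` ("scale"), 0.01 and 0.001.
#'
#' @param p feature count (sets the "scale" gamma).
#' @return data.frame with columns `kernel`, `cost`, `gamma`.
#' @export
svmDefaultGrid <- function(p) {
  costs <- c(0.1, 1, 10, 100)
  rbind(data.frame(kernel = "linear", cost = costs, gamma = NA_real_),
        expand.grid(kernel = "radial", cost = costs,
                    gamma = c(1 / p, 0.01, 0.001),
                    stringsAsFactors = FALSE))
}

#' Train and validate an SVM on subtype pseudo-labels
#'
#' Stratified 70/30 train/test split; hyperparameters chosen by grid
#' search with stratified `cvFolds`-fold cross-validated accuracy on the
#' training split only; the selected model is refit on the full training
#' split and evaluated on the held-out test split by accuracy and, when a
#' survival table is supplied, by the log-rank test between predicted
#' groups (significant at 0.05).
#'
#' @param x samples x features matrix (e.g. from
#'   [buildClassifierMatrix()]).
#' @param labels cluster pseudo-labels per sample (a [SubtypeCall-class]
#'   or an integer vector).
#' @param survival optional data.frame with `time` and `event` aligned to
#'   `x`.
#' @param split training fraction (default 0.7).
#' @param cvFolds cross-validation folds for the grid search.
#' @param grid hyperparameter data.frame (see [svmDefaultGrid()]).
#' @param seed integer seed (split, folds).
#' @return list with `best` (chosen hyperparameters), `cvAccuracy`,
#'   `trainIdx`, `testIdx`, `predicted` (test-set labels), `accuracy`,
#'   `logrankP` (or `NA`), `seed`.
#' @export
trainValidateSVM <- function(x, labels, survival = NULL, split = 0.7,
                             cvFolds = 5L, grid = NULL, seed = 1L) {
  X <- as.matrix(x)
  if (is(labels, "SubtypeCall")) labels <- subtypeLabels(labels)
  y <- factor(labels)
  stopifnot(nrow(X) == length(y))
  if (is.null(grid)) grid <- svmDefaultGrid(ncol(X))
  set.seed(seed)
  trainIdx <- .stratifiedSplit(y, split)
  testIdx <- setdiff(seq_len(nrow(X)), trainIdx)
  yTr <- droplevels(y[trainIdx])
  if (min(table(yTr)) < cvFolds)
    stop("a class has fewer members than cvFolds in the training split; ",
         "re-seed or reduce cvFolds")
  fold <- .stratifiedFolds(yTr, cvFolds)
  cvAcc <- vapply(seq_len(nrow(grid)), function(r) {
    accs <- vapply(seq_len(cvFolds), function(f) {
      tr <- trainIdx[fold != f]; va <- trainIdx[fold == f]
      fit <- .fitSVM(X[tr, , drop = FALSE], droplevels(y[tr]), grid[r, ])
      mean(predict(fit, X[va, , drop = FALSE]) == y[va])
    }, 0)
    mean(accs)
  }, 0)
  best <- grid[which.max(cvAcc), ]
  fit <- .fitSVM(X[trainIdx, , drop = FALSE], yTr, best)
  pred <- predict(fit, X[testIdx, , drop = FALSE])
  acc <- mean(pred == y[testIdx])
  lrP <- NA_real_
  if (!is.null(survival) && length(unique(pred)) >= 2L)
    lrP <- tryCatch(
      logrankTest(survival[testIdx, , drop = FALSE], as.character(pred))$p,
      error = function(e) NA_real_)
  list(best = best, cvAccuracy = max(cvAcc), trainIdx = trainIdx,
       testIdx = testIdx, predicted = pred, accuracy = acc, logrankP = lrP,
       seed = seed)
}

.fitSVM <- function(X, y, row) {
  if (row$kernel == "linear")
    e1071::svm(X, y, kernel = "linear", cost = row$cost, scale = FALSE)
  else
    e1071::svm(X, y, kernel = "radial", cost = row$cost, gamma = row$gamma,
               scale = FALSE)
}

#' Chi-square association between subtypes and a categorical covariate
#'
#' Builds the subtype x covariate contingency table (missing covariate
#' values dropped), computes `chi2 = sum (O - E)^2 / E` with expectations
#' from the row/column margins, `df = (r - 1)(c - 1)`, and the effect size
#' `Cramer's V = sqrt(chi2 / (n * min(r - 1, c - 1)))`.  No continuity
#' correction is applied (set `yates = TRUE` for the corrected 2x2
#' statistic).  A zero expected cell is a hard error (collapse sparse
#' categories upstream); expected cells below 5 raise a warning only.
#'
#' @param labels subtype label per sample.
#' @param covariate categorical covariate per sample (NA = missing).
#' @param name covariate name carried into the result.
#' @param yates apply the Yates continuity correction (2x2 only).
#' @return list with `name`, `table`, `chisq`, `df`, `p`, `cramersV`,
#'   `significant` (at 0.05), `n`.
#' @export
chiSquareAssociation <- function(labels, covariate, name = "covariate",
                                 yates = FALSE) {
  keep <- !is.na(covariate) & covariate != ""
  labels <- as.character(labels)[keep]
  covariate <- as.character(covariate)[keep]
  tab <- table(subtype = labels, covariate = covariate)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("association needs >= 2 subtype levels and >= 2 covariate levels")
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  if (any(E == 0))
    stop("zero expected cell; collapse sparse categories upstream")
  if (any(E < 5))
    warning("expected cell counts below 5; chi-square approximation weak")
  diffs <- abs(tab - E)
  if (yates && nrow(tab) == 2L && ncol(tab) == 2L)
    diffs <- pmax(diffs - 0.5, 0)
  chisq <- sum(diffs^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p <- pchisq(chisq, df, lower.tail = FALSE)
  V <- sqrt(chisq / (n * min(nrow(tab) - 1L, ncol(tab) - 1L)))
  list(name = name, table = tab, chisq = chisq, df = df, p = p,
       cramersV = V, significant = p < 0.05, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
fdrAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

.entropy <- function(counts) {
  pr <- counts / sum(counts)
  pr <- pr[pr > 0]
  -sum(pr * log(pr))
}

#' Agreement between two clusterings (ARI and NMI)
#'
#' Adjusted Rand Index via the pair-counting adjusted-for-chance formula
#' and Normalized Mutual Information with arithmetic-mean normalization
#' `NMI = I(A; B) / ((H(A) + H(B)) / 2)`.  Both equal 1 for identical
#' labelings (up to renaming); degenerate single-cluster pairs are scored
#' 1 when identical.
#'
#' @param labelsA,labelsB cluster labels over the same samples.
#' @return list with `ari`, `nmi` and the `table` of the two labelings.
#' @export
clusteringAgreement <- function(labelsA, labelsB) {
  stopifnot(length(labelsA) == length(labelsB))
  n <- length(labelsA)
  if (n < 2L) stop("agreement needs at least 2 samples")
  tab <- table(A = as.character(labelsA), B = as.character(labelsB))
  a <- rowSums(tab); b <- colSums(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumA <- sum(comb2(a)); sumB <- sum(comb2(b))
  expected <- sumA * sumB / comb2(n)
  maxIdx <- (sumA + sumB) / 2
  ari <- if (maxIdx == expected) 1 else (sumIJ - expected) /
    (maxIdx - expected)
  hA <- .entropy(a); hB <- .entropy(b)
  if (hA + hB == 0) {
    nmi <- 1
  } else {
    mi <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij > 0)
        mi <- mi + (nij / n) * log(nij * n / (a[i] * b[j]))
    }
    nmi <- mi / ((hA + hB) / 2)
  }
  list(ari = as.numeric(ari), nmi = as.numeric(nmi), table = tab)
}
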