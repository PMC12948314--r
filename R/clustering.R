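## K-means subtype discovery (Lloyd iterations, seeded restarts, empty
## cluster reseeding, size-canonicalized labels) with silhouette, CH, DB
## and GMM-BIC diagnostics, and survival-aware selection of the cluster
## number over k = 2..5.

#' @importFrom mclust Mclust mclustBIC
NULL

.sqDistToCenters <- function(X, C) {
  ## n x k matrix of squared Euclidean distances
  xs <- rowSums(X^2)
  cs <- rowSums(C^2)
  d2 <- outer(xs, cs, "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

.lloyd <- function(X, k, initIdx, maxIter, tol) {
  C <- X[initIdx, , drop = FALSE]
  jHist <- numeric(0)
  labels <- NULL
  for (it in seq_len(maxIter)) {
    d2 <- .sqDistToCenters(X, C)
    labels <- max.col(-d2, ties.method = "first")
    ## empty clusters: reseed at the point farthest from its centroid
    repeat {
      sizes <- tabulate(labels, nbins = k)
      empty <- which(sizes == 0L)
      if (!length(empty)) break
      far <- which.max(d2[cbind(seq_len(nrow(X)), labels)])
      C[empty[1L], ] <- X[far, ]
      d2 <- .sqDistToCenters(X, C)
      labels <- max.col(-d2, ties.method = "first")
    }
    J <- sum(d2[cbind(seq_len(nrow(X)), labels)])
    jHist <- c(jHist, J)
    Cnew <- C
    for (g in seq_len(k))
      Cnew[g, ] <- colMeans(X[labels == g, , drop = FALSE])
    move <- max(abs(Cnew - C))
    C <- Cnew
    if (move < tol) break
  }
  d2 <- .sqDistToCenters(X, C)
  labels <- max.col(-d2, ties.method = "first")
  J <- sum(d2[cbind(seq_len(nrow(X)), labels)])
  jHist <- c(jHist, J)
  if (any(diff(jHist) > 1e-8 * max(jHist[1L], 1)))
    warning("K-means objective increased across Lloyd iterations")
  list(labels = labels, centers = C, J = J, jHist = jHist)
}

#' K-means clustering of latent features
#'
#' Lloyd iterations minimizing the objective
#' `J = sum_i sum_{x in C_i} || x - mu_i ||^2` until the maximal centroid
#' movement falls below `tol` or `maxIter` is reached; the best of `nInit`
#' seeded random restarts (by `J`) is kept.  An empty cluster is reseeded
#' at the point farthest from its current centroid.  Labels are
#' canonicalized by descending cluster size (ties by first occurrence) so
#' assignments are comparable across runs.
#'
#' @param x samples x features numeric matrix.
#' @param k number of clusters (`k = 1` is allowed for diagnostics such as
#'   the total sum of squares).
#' @param seed integer seed.
#' @param nInit number of random restarts.
#' @param maxIter,tol Lloyd stopping rule.
#' @return A [SubtypeCall-class].
#' @export
kmeansCluster <- function(x, k, seed = 1L, nInit = 10L, maxIter = 300L,
                          tol = 1e-6) {
  X <- as.matrix(x)
  n <- nrow(X)
  stopifnot(k >= 1L, k <= n)
  set.seed(seed)
  best <- NULL
  for (i in seq_len(nInit)) {
    initIdx <- sample.int(n, k)
    run <- .lloyd(X, k, initIdx, maxIter, tol)
    if (is.null(best) || run$J < best$J) best <- run
  }
  ## canonicalize: relabel clusters by descending size, ties by first seen
  sizes <- tabulate(best$labels, nbins = k)
  ord <- order(-sizes, match(seq_len(k), unique(best$labels)))
  relab <- integer(k); relab[ord] <- seq_len(k)
  labels <- relab[best$labels]
  centers <- best$centers[ord, , drop = FALSE]
  names(labels) <- rownames(X)
  new("SubtypeCall", labels = as.integer(labels), k = as.integer(k),
      objective = best$J, centers = centers,
      diagnostics = data.frame(), seed = as.integer(seed))
}

#' Mean silhouette coefficient
#'
#' Per sample, `S_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean
#' distance to the other members of its cluster and `b_i` the smallest
#' mean distance to the members of any other cluster; samples in singleton
#' clusters score 0.  Returns the mean over samples, in `[-1, 1]`.
#'
#' @param x samples x features matrix.
#' @param labels integer cluster label per sample (>= 2 distinct values).
#' @return Mean silhouette width.
#' @export
silhouetteScore <- function(x, labels) {
  X <- as.matrix(x)
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette is undefined for a single cluster")
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  sizes <- table(factor(labels, levels = ks))
  ## mean distance from each point to each cluster
  agg <- vapply(ks, function(g) rowSums(D[, labels == g, drop = FALSE]),
                numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    gi <- match(labels[i], ks)
    ni <- sizes[gi]
    if (ni == 1L) { s[i] <- 0; next }
    a <- agg[i, gi] / (ni - 1)
    b <- min(agg[i, -gi] / sizes[-gi])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Cluster-validity diagnostics: CH, DB and GMM-BIC
#'
#' Calinski-Harabasz index (between- over within-cluster dispersion,
#' higher is better), Davies-Bouldin index (mean over clusters of the
#' worst-case compactness-to-separation ratio, lower is better), and the
#' Bayesian Information Criterion of a diagonal-covariance Gaussian
#' mixture with `k` components fitted to the matrix (conventional sign:
#' lower is better).
#'
#' @param x samples x features matrix with positive total variance.
#' @param labels integer cluster labels (k >= 2 groups).
#' @param seed seed forwarded to the GMM fit.
#' @return list with `CH`, `DB` and `BIC`.
#' @export
clusteringDiagnostics <- function(x, labels, seed = 1L) {
  X <- as.matrix(x)
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2L) stop("diagnostics require at least 2 clusters")
  n <- nrow(X)
  if (sum(apply(X, 2L, var)) == 0)
    stop("zero-variance matrix: diagnostics are undefined")
  grand <- colMeans(X)
  centers <- t(vapply(ks, function(g) colMeans(X[labels == g, , drop = FALSE]),
                      numeric(ncol(X))))
  sizes <- vapply(ks, function(g) sum(labels == g), 0L)
  Bdisp <- sum(sizes * rowSums(sweep(centers, 2L, grand, "-")^2))
  Wdisp <- sum(vapply(seq_along(ks), function(gi) {
    sub <- X[labels == ks[gi], , drop = FALSE]
    sum(sweep(sub, 2L, centers[gi, ], "-")^2)
  }, 0))
  CH <- (Bdisp / (k - 1)) / (Wdisp / (n - k))
  sbar <- vapply(seq_along(ks), function(gi) {
    sub <- X[labels == ks[gi], , drop = FALSE]
    mean(sqrt(rowSums(sweep(sub, 2L, centers[gi, ], "-")^2)))
  }, 0)
  Dc <- as.matrix(stats::dist(centers))
  DB <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (sbar[i] + sbar[j]) / Dc[i, j], 0))
  }, 0))
  BIC <- .gmmBIC(X, k, seed)
  list(CH = CH, DB = DB, BIC = BIC)
}

## Conventional BIC (-2 loglik + penalty) of a diagonal GMM via mclust.
.gmmBIC <- function(X, k, seed = 1L) {
  set.seed(seed)
  model <- if (ncol(X) == 1L) "V" else "VVI"
  fit <- tryCatch(
    mclust::Mclust(X, G = k, modelNames = model, verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$bic) || !is.finite(fit$bic)) {
    ## fall back to equal-variance diagonal model on hard fits
    fit <- mclust::Mclust(X, G = k, modelNames = if (ncol(X) == 1L) "E"
                          else "EEI", verbose = FALSE)
  }
  -as.numeric(fit$bic)     # mclust reports 2*loglik - penalty
}

#' Select the number of subtypes over a k range
#'
#' For each `k` in `kRange` the latent matrix is clustered and scored by
#' mean silhouette and by the log-rank test across the resulting groups.
#' The chosen `k` minimizes the log-rank p-value among those k whose
#' silhouette is within `silhouetteGate` (default 90%) of the best
#' silhouette; geometry gates the candidates, survival separation decides.
#' If every log-rank test is degenerate (e.g. no events) the
#' max-silhouette k is returned with a warning.  All per-k diagnostics
#' (silhouette, log-rank p, CH, DB, BIC) are reported in the result's
#' `diagnostics` slot.
#'
#' @param x samples x features latent matrix.
#' @param survival data.frame with `time` and `event`, rows aligned to `x`.
#' @param kRange candidate cluster numbers (default `2:5`).
#' @param seed integer seed.
#' @param nInit restarts per k (see [kmeansCluster()]).
#' @param silhouetteGate fraction of the best silhouette a k must reach to
#'   stay a candidate.
#' @return A [SubtypeCall-class] for the chosen k, with the per-k table in
#'   its `diagnostics` slot.
#' @export
selectNumClusters <- function(x, survival, kRange = 2:5, seed = 1L,
                              nInit = 10L, silhouetteGate = 0.9) {
  X <- as.matrix(x)
  stopifnot(max(kRange) <= nrow(X), all(kRange >= 2L))
  calls <- list()
  rows <- lapply(seq_along(kRange), function(i) {
    k <- kRange[i]
    call <- kmeansCluster(X, k, seed = seed + i - 1L, nInit = nInit)
    calls[[as.character(k)]] <<- call
    sil <- silhouetteScore(X, subtypeLabels(call))
    diag <- clusteringDiagnostics(X, subtypeLabels(call), seed = seed)
    p <- tryCatch(logrankTest(survival, subtypeLabels(call))$p,
                  error = function(e) NA_real_)
    data.frame(k = k, silhouette = sil, logrankP = p, CH = diag$CH,
               DB = diag$DB, BIC = diag$BIC)
  })
  tab <- do.call(rbind, rows)
  gate <- tab$silhouette >= silhouetteGate * max(tab$silhouette)
  cand <- tab[gate & is.finite(tab$logrankP), , drop = FALSE]
  if (!nrow(cand)) {
    warning("all log-rank tests degenerate; falling back to the ",
            "max-silhouette k")
    kSel <- tab$k[which.max(tab$silhouette)]
  } else {
    kSel <- cand$k[which.min(cand$logrankP)]   # ties -> smaller k
  }
  out <- calls[[as.character(kSel)]]
  out@diagnostics <- tab
  out
}
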