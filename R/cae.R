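## Convolutional autoencoder with channel attention for one omics layer.
## Encoder: two strided 1-D convolutions -> attention gate -> dense latent.
## Decoder mirrors the encoder with nearest-neighbour upsampling + conv,
## ending in a sigmoid (inputs are min-max normalized to [0,1]).

#' Configuration for the attention CAE
#'
#' Defaults: two encoder convolutions with 8 then 16 channels, kernel 5,
#' stride 2; channel attention (reduction ratio `r = 8`) after the last
#' encoder convolution; a dense map to `latentDim` latent features; Adam at
#' learning rate 1e-3 minimizing mean squared reconstruction error for 100
#' epochs at batch size 16.  `variant = "no_attention"` replaces the
#' attention block by the identity (the ablation path).
#'
#' @param latentDim latent dimensionality (>= 1 and < the number of input
#'   features at training time).
#' @param convChannels integer vector of length 2, encoder channel widths.
#' @param kernelSize odd convolution kernel width.
#' @param stride convolution stride (2).
#' @param r attention reduction ratio; hidden width is `ceiling(C / r)`.
#' @param epochs,batchSize,learningRate optimizer settings.
#' @param weightDecay decoupled L2 decay applied to weights (not biases)
#'   at each Adam step; counteracts per-sample memorization on small
#'   cohorts, which degrades the latent geometry late in training.
#' @param seed integer seed controlling initialization and batch order.
#' @param variant `"full"` or `"no_attention"`.
#' @return A named list of class `caeConfig`.
#' @export
caeConfig <- function(latentDim = 100L, convChannels = c(8L, 16L),
                      kernelSize = 5L, stride = 2L, r = 8L,
                      epochs = 100L, batchSize = 16L, learningRate = 1e-3,
                      weightDecay = 3, seed = 1L,
                      variant = c("full", "no_attention")) {
  variant <- match.arg(variant)
  stopifnot(latentDim >= 1L, length(convChannels) == 2L,
            kernelSize %% 2L == 1L, stride == 2L, r >= 1L,
            epochs >= 1L, batchSize >= 1L, learningRate > 0,
            weightDecay >= 0)
  structure(list(latentDim = as.integer(latentDim),
                 convChannels = as.integer(convChannels),
                 kernelSize = as.integer(kernelSize),
                 stride = as.integer(stride), r = as.integer(r),
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, weightDecay = weightDecay,
                 seed = as.integer(seed), variant = variant),
            class = "caeConfig")
}

.caeArch <- function(nFeatures, config) {
  k <- config$kernelSize; s <- config$stride; p <- k %/% 2L
  L1 <- (nFeatures + 2L * p - k) %/% s + 1L
  L2 <- (L1 + 2L * p - k) %/% s + 1L
  if (L2 < 1L) stop("too few features for the convolutional stack")
  list(nF = as.integer(nFeatures), k = k, s = s, p = p,
       c1 = config$convChannels[1L], c2 = config$convChannels[2L],
       L1 = L1, L2 = L2, latent = config$latentDim,
       r = config$r, attention = config$variant == "full")
}

.heMat <- function(nr, nc, fanIn) matrix(rnorm(nr * nc, sd = sqrt(2 / fanIn)),
                                         nr, nc)

.caeInit <- function(arch) {
  k <- arch$k
  params <- list(
    convW1 = .heMat(k * 1L, arch$c1, k),
    convB1 = numeric(arch$c1),
    convW2 = .heMat(k * arch$c1, arch$c2, k * arch$c1),
    convB2 = numeric(arch$c2),
    encW = .heMat(arch$L2 * arch$c2, arch$latent, arch$L2 * arch$c2),
    encB = numeric(arch$latent),
    decW = .heMat(arch$latent, arch$L2 * arch$c2, arch$latent),
    decB = numeric(arch$L2 * arch$c2),
    convW3 = .heMat(k * arch$c2, arch$c1, k * arch$c2),
    convB3 = numeric(arch$c1),
    convW4 = .heMat(k * arch$c1, 1L, k * arch$c1),
    convB4 = numeric(1L))
  if (arch$attention) {
    H <- max(1L, ceiling(arch$c2 / arch$r))
    params$attW1 <- .heMat(H, arch$c2, arch$c2)
    params$attB1 <- numeric(H)
    params$attW2 <- .heMat(arch$c2, H, H)
    params$attB2 <- numeric(arch$c2)
  }
  params
}

.caeEncodeForward <- function(params, X, arch, keepCache = FALSE) {
  B <- nrow(X)
  X3 <- array(X, c(B, arch$nF, 1L))
  cv1 <- .convForward(X3, params$convW1, params$convB1, arch$k, arch$s,
                      arch$p)
  a1 <- pmax(cv1$out, 0)
  cv2 <- .convForward(a1, params$convW2, params$convB2, arch$k, arch$s,
                      arch$p)
  a2 <- pmax(cv2$out, 0)
  att <- NULL
  if (arch$attention) {
    att <- .attnForward(a2, list(W1 = params$attW1, b1 = params$attB1,
                                 W2 = params$attW2, b2 = params$attB2))
    a2a <- att$out
  } else a2a <- a2
  flat <- matrix(a2a, B, arch$L2 * arch$c2)
  dn <- .denseForward(flat, params$encW, params$encB)
  res <- list(latent = dn$out)
  if (keepCache)
    res$cache <- list(cv1 = cv1, a1 = a1, cv2 = cv2, a2 = a2, att = att,
                      flat = flat, dn = dn, B = B)
  res
}

.caeForward <- function(params, X, arch) {
  B <- nrow(X)
  enc <- .caeEncodeForward(params, X, arch, keepCache = TRUE)
  dd <- .denseForward(enc$latent, params$decW, params$decB)
  h <- pmax(dd$out, 0)
  h3 <- array(h, c(B, arch$L2, arch$c2))
  up1 <- .upsampleForward(h3, arch$s, arch$L1)
  cv3 <- .convForward(up1$out, params$convW3, params$convB3, arch$k, 1L,
                      arch$p)
  a3 <- pmax(cv3$out, 0)
  up2 <- .upsampleForward(a3, arch$s, arch$nF)
  cv4 <- .convForward(up2$out, params$convW4, params$convB4, arch$k, 1L,
                      arch$p)
  recon <- .sigmoid(cv4$out)
  list(recon = matrix(recon, B, arch$nF), enc = enc,
       cache = list(dd = dd, h = h, up1 = up1, cv3 = cv3, a3 = a3,
                    up2 = up2, cv4 = cv4, recon = recon, B = B))
}

.caeLossGrad <- function(params, X, arch) {
  fw <- .caeForward(params, X, arch)
  B <- nrow(X)
  diff <- fw$recon - X
  loss <- mean(diff^2)
  grads <- lapply(params, function(p) p * 0)

  dRecon <- array(2 * diff / length(diff), c(B, arch$nF, 1L))
  dPre4 <- dRecon * fw$cache$recon * (1 - fw$cache$recon)
  b4 <- .convBackward(dPre4, fw$cache$cv4$cache)
  grads$convW4 <- b4$dW; grads$convB4 <- b4$db
  dA3 <- .upsampleBackward(b4$dX, fw$cache$up2$cache)
  dPre3 <- dA3 * (fw$cache$cv3$out > 0)
  b3 <- .convBackward(dPre3, fw$cache$cv3$cache)
  grads$convW3 <- b3$dW; grads$convB3 <- b3$db
  dH3 <- .upsampleBackward(b3$dX, fw$cache$up1$cache)
  dH <- matrix(dH3, B, arch$L2 * arch$c2) * (fw$cache$dd$out > 0)
  bDec <- .denseBackward(dH, fw$cache$dd$cache)
  grads$decW <- bDec$dW; grads$decB <- bDec$db

  ec <- fw$enc$cache
  bEnc <- .denseBackward(bDec$dX, ec$dn$cache)
  grads$encW <- bEnc$dW; grads$encB <- bEnc$db
  dFlat <- array(bEnc$dX, c(B, arch$L2, arch$c2))
  if (arch$attention) {
    bAtt <- .attnBackward(dFlat, ec$att$cache)
    grads$attW1 <- bAtt$dW1; grads$attB1 <- bAtt$db1
    grads$attW2 <- bAtt$dW2; grads$attB2 <- bAtt$db2
    dA2 <- bAtt$dX
  } else dA2 <- dFlat
  dPre2 <- dA2 * (ec$cv2$out > 0)
  b2 <- .convBackward(dPre2, ec$cv2$cache)
  grads$convW2 <- b2$dW; grads$convB2 <- b2$db
  dA1 <- b2$dX * (ec$cv1$out > 0)
  b1 <- .convBackward(dA1, ec$cv1$cache, needDX = FALSE)
  grads$convW1 <- b1$dW; grads$convB1 <- b1$db

  list(loss = loss, grads = grads)
}

#' Train the attention CAE on a preprocessed omics layer
#'
#' Minimizes mean squared reconstruction error with Adam on mini-batches.
#' The input should be min-max normalized (and typically
#' correlation-reordered); training is deterministic for a fixed seed.
#'
#' @param layer an [OmicsLayer-class] or numeric samples x features matrix,
#'   values in `[0, 1]`.
#' @param config a [caeConfig()] list.
#' @return A [TrainedCAE-class].
#' @export
trainCAE <- function(layer, config = caeConfig()) {
  X <- if (is(layer, "OmicsLayer")) as.matrix(layer) else as.matrix(layer)
  n <- nrow(X); nF <- ncol(X)
  if (config$latentDim >= nF)
    stop("latentDim must be smaller than the input feature count")
  if (config$batchSize > n)
    stop("batch size exceeds sample count")
  arch <- .caeArch(nF, config)
  set.seed(config$seed)
  params <- .caeInit(arch)
  opt <- .adamInit(params)
  lossHist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batchSize)
    epLoss <- 0
    for (s0 in starts) {
      idx <- perm[s0:min(s0 + config$batchSize - 1L, n)]
      lg <- .caeLossGrad(params, X[idx, , drop = FALSE], arch)
      if (!is.finite(lg$loss))
        stop("non-finite training loss; reduce the learning rate")
      st <- .adamStep(params, lg$grads, opt, config$learningRate,
                      weightDecay = config$weightDecay)
      params <- st$params; opt <- st$state
      epLoss <- epLoss + lg$loss * length(idx)
    }
    lossHist[ep] <- epLoss / n
  }
  fp <- colnames(X)
  if (is.null(fp)) fp <- as.character(seq_len(nF))
  new("TrainedCAE", params = params, lossHistory = lossHist,
      config = unclass(config), featureFingerprint = fp)
}

.encodeMatrix <- function(model, X) {
  fp <- colnames(X)
  if (is.null(fp)) fp <- as.character(seq_len(ncol(X)))
  if (!identical(fp, model@featureFingerprint))
    stop("feature order does not match the model's training fingerprint")
  cfg <- model@config
  class(cfg) <- "caeConfig"
  arch <- .caeArch(ncol(X), cfg)
  lat <- .caeEncodeForward(model@params, X, arch)$latent
  rownames(lat) <- rownames(X)
  colnames(lat) <- paste0("z", seq_len(ncol(lat)))
  lat
}

#' @describeIn TrainedCAE-class encode an [OmicsLayer-class]
#' @param model,x see generic
#' @export
setMethod("encodeSamples", signature("TrainedCAE", "OmicsLayer"),
          function(model, x) .encodeMatrix(model, as.matrix(x)))

#' @describeIn TrainedCAE-class encode a plain matrix
#' @export
setMethod("encodeSamples", signature("TrainedCAE", "matrix"),
          function(model, x) .encodeMatrix(model, x))

#' Baseline linear reducers (PCA, NMF)
#'
#' Drop-in replacements for the CAE encoder used in benchmark comparisons:
#' only the feature-extraction step changes, everything downstream is
#' identical.  PCA returns the first `nComponents` principal-component
#' scores (sign fixed so the largest-magnitude loading is positive); NMF
#' factorizes the nonnegative matrix `X ~ W H` by Lee-Seung multiplicative
#' updates for the Frobenius objective and returns `W`.
#'
#' @param layer an [OmicsLayer-class] or numeric matrix (nonnegative for
#'   NMF; guaranteed after min-max normalization).
#' @param method `"pca"` or `"nmf"`.
#' @param nComponents number of reduced dimensions.
#' @param seed seed for the NMF initialization (PCA is deterministic).
#' @param maxIter,tol NMF stopping rule (relative objective change).
#' @return samples x `nComponents` score matrix.
#' @export
baselineReduce <- function(layer, method = c("pca", "nmf"), nComponents,
                           seed = 1L, maxIter = 300L, tol = 1e-8) {
  method <- match.arg(method)
  X <- if (is(layer, "OmicsLayer")) as.matrix(layer) else as.matrix(layer)
  n <- nrow(X); p <- ncol(X)
  if (nComponents > min(n - 1L, p))
    stop("nComponents exceeds the rank bound min(n - 1, p)")
  if (method == "pca") {
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    flip <- vapply(seq_len(nComponents), function(j) {
      l <- pc$rotation[, j]
      sign(l[which.max(abs(l))])
    }, 0)
    scores <- sweep(pc$x[, seq_len(nComponents), drop = FALSE], 2L, flip,
                    "*")
  } else {
    if (any(X < 0)) stop("NMF requires nonnegative input")
    set.seed(seed)
    W <- matrix(runif(n * nComponents, 0.1, 1), n, nComponents)
    H <- matrix(runif(nComponents * p, 0.1, 1), nComponents, p)
    eps <- 1e-10
    prev <- Inf
    for (it in seq_len(maxIter)) {
      H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
      W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
      obj <- sum((X - W %*% H)^2)
      if (is.finite(prev) && abs(prev - obj) <= tol * max(prev, eps)) break
      prev <- obj
    }
    scores <- W
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0(method, seq_len(nComponents))
  scores
}
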