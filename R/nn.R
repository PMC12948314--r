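## Minimal neural-network primitives used by the convolutional autoencoder:
## 1-D convolution (im2col), dense layers, nearest-neighbour upsampling and
## Adam.  All tensors are (batch, length, channels) arrays; everything is
## plain double-precision R backed by BLAS matrix products, which keeps
## training deterministic for a fixed seed on fixed hardware.

.convIndex <- function(Lp, k, stride) {
  Lout <- (Lp - k) %/% stride + 1L
  outer(seq_len(Lout) - 1L, seq_len(k), function(t, kk) t * stride + kk)
}

.pad3 <- function(X, pad) {
  if (pad == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1L], d[2L] + 2L * pad, d[3L]))
  Xp[, pad + seq_len(d[2L]), ] <- X
  Xp
}

## X: (B, L, Cin); W: (k*Cin, Cout), columns of the patch matrix ordered
## kernel-position-fastest within channel.  The patch gather (im2col) and
## its transpose scatter (col2im) are compiled; matrix products use BLAS.
.convForward <- function(X, W, b, k, stride, pad) {
  d <- dim(X)
  Xp <- .pad3(X, pad)
  Lp <- dim(Xp)[2L]
  I2 <- .convIndex(Lp, k, stride)
  Lout <- nrow(I2)
  Xm <- .im2colC(Xp, c(d[1L], Lp, d[3L]), I2)
  Y <- Xm %*% W
  Y <- sweep(Y, 2L, b, "+")
  dim(Y) <- c(d[1L], Lout, ncol(W))
  list(out = Y, cache = list(Xm = Xm, I2 = I2, dimX = d, pad = pad,
                             k = k, Lp = Lp, Lout = Lout, W = W))
}

.convBackward <- function(dY, cache, needDX = TRUE) {
  d <- cache$dimX
  Lout <- cache$Lout
  Cout <- dim(dY)[3L]
  dYm <- matrix(dY, d[1L] * Lout, Cout)
  dW <- crossprod(cache$Xm, dYm)
  db <- colSums(dYm)
  if (!needDX) return(list(dX = NULL, dW = dW, db = db))
  B <- d[1L]; Cin <- d[3L]; Lp <- cache$Lp
  dXc <- dYm %*% t(cache$W)                    # (B*Lout, k*Cin)
  dXp <- .col2imC(dXc, c(B, Lp, Cin), cache$I2)
  dX <- dXp[, cache$pad + seq_len(d[2L]), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

## Nearest-neighbour upsampling by integer factor, cropped to targetL.
.upsampleForward <- function(X, factor, targetL) {
  idx <- ceiling(seq_len(targetL) / factor)
  list(out = X[, idx, , drop = FALSE],
       cache = list(factor = factor, targetL = targetL, Lin = dim(X)[2L],
                    dimX = dim(X)))
}

.upsampleBackward <- function(dY, cache) {
  d <- cache$dimX
  B <- d[1L]; Lin <- d[2L]; C <- d[3L]
  dXm <- matrix(0, B, Lin * C)
  chOffIn <- (seq_len(C) - 1L) * Lin
  chOffOut <- (seq_len(C) - 1L) * cache$targetL
  dYm <- dY
  dim(dYm) <- c(B, cache$targetL * C)
  for (o in seq_len(cache$factor)) {
    ts <- seq(o, cache$targetL, by = cache$factor)
    if (!length(ts)) next
    js <- (ts - o) / cache$factor + 1L
    src <- as.vector(outer(ts, chOffOut, "+"))
    dst <- as.vector(outer(js, chOffIn, "+"))
    dXm[, dst] <- dXm[, dst] + dYm[, src]
  }
  dim(dXm) <- d
  dXm
}

.denseForward <- function(X, W, b) {
  Y <- X %*% W
  list(out = sweep(Y, 2L, b, "+"), cache = list(X = X, W = W))
}

.denseBackward <- function(dY, cache) {
  list(dX = dY %*% t(cache$W), dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

## Attention block training-time forward/backward (shared-MLP bottleneck).
.attnForward <- function(Fmap, p) {
  d <- dim(Fmap)
  pool <- channelPoolStats(Fmap)
  preA <- sweep(pool$avg %*% t(p$W1), 2L, p$b1, "+")
  preM <- sweep(pool$max %*% t(p$W1), 2L, p$b1, "+")
  hA <- pmax(preA, 0); hM <- pmax(preM, 0)
  M <- sweep(hA %*% t(p$W2), 2L, p$b2, "+") +
       sweep(hM %*% t(p$W2), 2L, p$b2, "+")
  g <- .sigmoid(M)
  gB <- aperm(array(g, c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
  list(out = Fmap * gB,
       cache = list(Fmap = Fmap, pool = pool, hA = hA, hM = hM,
                    g = g, gB = gB, p = p, d = d))
}

.attnBackward <- function(dY, cache) {
  d <- cache$d; p <- cache$p; g <- cache$g
  B <- d[1L]; L <- d[2L]; C <- d[3L]
  dF <- dY * cache$gB
  ## dg[b,c] = sum_t dY[b,t,c] * F[b,t,c]
  prod <- dY * cache$Fmap
  dg <- matrix(rowSums(matrix(aperm(prod, c(1L, 3L, 2L)), B * C, L)), B, C)
  dM <- dg * g * (1 - g)
  branch <- function(h, v) {
    dW2 <- crossprod(dM, h)              # (C x H)
    db2 <- colSums(dM)
    dh <- (dM %*% p$W2) * (h > 0)
    dW1 <- crossprod(dh, v)              # (H x C)
    db1 <- colSums(dh)
    list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2, dv = dh %*% p$W1)
  }
  bA <- branch(cache$hA, cache$pool$avg)
  bM <- branch(cache$hM, cache$pool$max)
  ## average-pool branch spreads its gradient evenly over positions
  dF <- dF + aperm(array(bA$dv / L, c(B, C, L)), c(1L, 3L, 2L))
  ## max-pool branch routes gradient to the argmax position per channel
  bi <- rep(seq_len(B), C)
  ci <- rep(seq_len(C), each = B)
  ti <- as.vector(cache$pool$argmax)
  lin <- bi + (ti - 1L) * B + (ci - 1L) * B * L
  dF[lin] <- dF[lin] + as.vector(bM$dv)
  list(dX = dF,
       dW1 = bA$dW1 + bM$dW1, db1 = bA$db1 + bM$db1,
       dW2 = bA$dW2 + bM$dW2, db2 = bA$db2 + bM$db2)
}

.adamInit <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weightDecay = 0) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) +
                                              eps)
    ## decoupled weight decay on weights, not biases
    if (weightDecay > 0 && grepl("W", nm))
      step <- step + lr * weightDecay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}
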