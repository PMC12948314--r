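## Channel attention block: global average + max pooling per channel, a
## shared two-layer bottleneck MLP applied to both pooled vectors, additive
## combination, and a sigmoid gate multiplied back onto the feature map.
## Feature maps are (batch, L, C) arrays: omics inputs are 1-D signals, so
## the usual H x W spatial grid collapses to a single length-L axis.

#' Global average and max pooling per channel
#'
#' For a feature map `F` of shape (batch, L, C), computes per channel c the
#' spatial mean `F_avg[c] = mean_t F[t, c]` and spatial maximum
#' `F_max[c] = max_t F[t, c]`, per batch element.
#'
#' @param fmap numeric array of shape (batch, L, C).
#' @return list with `avg` and `max`, each a (batch x C) matrix.
#' @export
channelPoolStats <- function(fmap) {
  stopifnot(is.array(fmap), length(dim(fmap)) == 3L)
  d <- dim(fmap)
  ## (B, L, C) -> (B, C, L) -> (B*C, L): rows are (batch, channel) pairs
  m <- matrix(aperm(fmap, c(1L, 3L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
  avg <- matrix(rowMeans(m), d[1L], d[3L])
  idx <- max.col(m, ties.method = "first")
  mx <- matrix(m[cbind(seq_len(nrow(m)), idx)], d[1L], d[3L])
  list(avg = avg, max = mx,
       argmax = matrix(idx, d[1L], d[3L]))  # used for backprop routing
}

#' Construct channel-attention parameters
#'
#' A shared bottleneck MLP: `W1` compresses C channels to `ceil(C / r)`
#' hidden units with ReLU, `W2` projects back to C.  The same weights serve
#' both the average-pool and max-pool branches.
#'
#' @param C channel count.
#' @param r reduction ratio (hidden width is `ceiling(C / r)`).
#' @param init standard deviation of the random normal initialization
#'   (0 gives all-zero parameters).
#' @return list with `W1` (hidden x C), `b1`, `W2` (C x hidden), `b2`, `r`.
#' @export
attentionParams <- function(C, r = 8L, init = 0) {
  H <- max(1L, ceiling(C / r))
  list(W1 = matrix(rnorm(H * C, sd = init), H, C),
       b1 = numeric(H),
       W2 = matrix(rnorm(C * H, sd = init), C, H),
       b2 = numeric(C),
       r = as.integer(r))
}

.sharedMLP <- function(v, params) {
  ## v: (B x C) matrix -> (B x C) logits via W2 %*% ReLU(W1 %*% v + b1) + b2
  h <- v %*% t(params$W1)
  h <- sweep(h, 2L, params$b1, "+")
  h <- pmax(h, 0)
  out <- h %*% t(params$W2)
  sweep(out, 2L, params$b2, "+")
}

#' Channel attention logits from pooled statistics
#'
#' Passes the average-pooled and max-pooled channel vectors through the
#' shared bottleneck MLP (`W2 %*% ReLU(W1 %*% v + b1) + b2`) and adds the
#' two branch outputs: `M = M_avg + M_max`.  The result is returned
#' pre-sigmoid; the squashing happens once, in [applyAttention()].
#'
#' @param fAvg,fMax (batch x C) matrices or length-C vectors from
#'   [channelPoolStats()].
#' @param params list from [attentionParams()].
#' @return (batch x C) matrix (or length-C vector for vector input) of
#'   unbounded attention logits.
#' @export
attentionWeights <- function(fAvg, fMax, params) {
  vec <- is.null(dim(fAvg))
  if (vec) { fAvg <- rbind(fAvg); fMax <- rbind(fMax) }
  C <- ncol(params$W1)
  if (ncol(fAvg) != C || ncol(fMax) != C)
    stop(sprintf("pooled vectors have %d channels but params expect %d",
                 ncol(fAvg), C))
  M <- .sharedMLP(fAvg, params) + .sharedMLP(fMax, params)
  if (vec) drop(M) else M
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Apply channel attention to a feature map
#'
#' `F' = F (.) sigmoid(M)`: each channel of the map is multiplied by its
#' sigmoid-squashed attention logit, broadcast over all spatial positions.
#'
#' @param fmap numeric array (batch, L, C).
#' @param M attention logits, (batch x C) matrix or length-C vector.
#' @return Array of the same shape as `fmap`.
#' @export
applyAttention <- function(fmap, M) {
  stopifnot(is.array(fmap), length(dim(fmap)) == 3L)
  d <- dim(fmap)
  if (is.null(dim(M))) M <- matrix(M, d[1L], length(M), byrow = TRUE)
  if (!identical(dim(M), d[c(1L, 3L)]))
    stop("channel count of M does not match the feature map")
  g <- .sigmoid(M)                       # (B x C)
  fmap * aperm(array(g, c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
}
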