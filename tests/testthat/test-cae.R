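## CAE training behaviour on a small separable fixture; heavier
## representation-quality checks live in the acceptance suite.

caeFixture <- function(seed = 1L, n = 60L, p = 40L) {
  set.seed(seed)
  grp <- rep(1:2, length.out = n)
  m <- matrix(rnorm(n * p, sd = 0.3), n, p) +
    outer(ifelse(grp == 1, 0.8, -0.8), c(rep(1, p / 2), rep(-1, p / 2)))
  m <- (m - min(m)) / (max(m) - min(m))
  dimnames(m) <- list(sprintf("s%03d", 1:n), sprintf("f%03d", 1:p))
  list(layer = OmicsLayer(m, "rna"), group = grp)
}

test_that("training reduces the reconstruction loss", {
  fx <- caeFixture()
  cfg <- caeConfig(latentDim = 4L, convChannels = c(4L, 8L), epochs = 20L,
                   batchSize = 20L, seed = 3L)
  m <- trainCAE(fx$layer, cfg)
  lh <- lossHistory(m)
  expect_length(lh, 20L)
  expect_lt(lh[20], lh[1])
  expect_true(all(is.finite(lh)))
})

test_that("training and encoding are deterministic given the seed", {
  fx <- caeFixture()
  cfg <- caeConfig(latentDim = 4L, convChannels = c(4L, 8L), epochs = 5L,
                   batchSize = 20L, seed = 11L)
  m1 <- trainCAE(fx$layer, cfg)
  m2 <- trainCAE(fx$layer, cfg)
  expect_identical(lossHistory(m1), lossHistory(m2))
  e1 <- encodeSamples(m1, fx$layer)
  e2 <- encodeSamples(m1, fx$layer)
  expect_identical(e1, e2)
  expect_identical(e1, encodeSamples(m2, fx$layer))
  expect_identical(dim(e1), c(60L, 4L))
})

test_that("the no-attention ablation trains and encodes on the same fixture", {
  fx <- caeFixture()
  cfg <- caeConfig(latentDim = 4L, convChannels = c(4L, 8L), epochs = 5L,
                   batchSize = 20L, seed = 3L, variant = "no_attention")
  m <- trainCAE(fx$layer, cfg)
  expect_false(any(grepl("^att", names(m@params))))
  e <- encodeSamples(m, fx$layer)
  expect_identical(dim(e), c(60L, 4L))
})

test_that("encoding refuses a mismatched feature order", {
  fx <- caeFixture()
  cfg <- caeConfig(latentDim = 4L, convChannels = c(4L, 8L), epochs = 2L,
                   batchSize = 20L, seed = 3L)
  m <- trainCAE(fx$layer, cfg)
  swapped <- as.matrix(fx$layer)[, c(2:1, 3:40)]
  expect_error(encodeSamples(m, swapped), "fingerprint")
})

test_that("latent space separates planted groups better than noise features", {
  fx <- caeFixture(seed = 5L)
  cfg <- caeConfig(latentDim = 4L, convChannels = c(4L, 8L), epochs = 30L,
                   batchSize = 20L, seed = 5L)
  m <- trainCAE(fx$layer, cfg)
  lat <- encodeSamples(m, fx$layer)
  silLatent <- silhouetteScore(lat, fx$group)
  set.seed(6)
  noise <- matrix(rnorm(60 * 4), 60, 4)
  silNoise <- silhouetteScore(noise, fx$group)
  expect_gt(silLatent, silNoise)
  expect_gt(silLatent, 0.2)
})

test_that("config validation rejects impossible settings", {
  fx <- caeFixture()
  expect_error(trainCAE(fx$layer, caeConfig(latentDim = 40L)),
               "latentDim")
  expect_error(trainCAE(fx$layer,
                        caeConfig(latentDim = 4L, batchSize = 500L)),
               "batch size")
})

test_that("PCA baseline: variances non-increasing, rank-1 data recovered", {
  set.seed(9)
  u <- rnorm(30); v <- rnorm(12)
  rank1 <- outer(u, v)
  dimnames(rank1) <- list(sprintf("s%02d", 1:30), sprintf("f%02d", 1:12))
  sc <- baselineReduce(rank1, "pca", nComponents = 1L)
  recon <- sc %*% (t(sc) %*% sweep(rank1, 2, colMeans(rank1))) /
    sum(sc^2)
  expect_lt(max(abs(sweep(rank1, 2, colMeans(rank1)) - recon)), 1e-8)
  full <- baselineReduce(matrix(rnorm(300), 30, 10,
                                dimnames = list(sprintf("s%02d", 1:30),
                                                paste0("f", 1:10))),
                         "pca", nComponents = 5L)
  vars <- apply(full, 2, var)
  expect_true(all(diff(vars) <= 1e-10))
  expect_error(baselineReduce(rank1, "pca", nComponents = 40L), "rank")
})

test_that("NMF baseline beats random factors and stays nonnegative", {
  set.seed(4)
  W0 <- matrix(runif(30 * 3), 30, 3); H0 <- matrix(runif(3 * 15), 3, 15)
  X <- W0 %*% H0
  dimnames(X) <- list(sprintf("s%02d", 1:30), sprintf("f%02d", 1:15))
  sc <- baselineReduce(X, "nmf", nComponents = 3L, seed = 2L)
  expect_true(all(sc >= 0))
  expect_identical(dim(sc), c(30L, 3L))
  ## reconstruction error must improve on the random initialization
  set.seed(2)
  Wr <- matrix(runif(30 * 3, 0.1, 1), 30, 3)
  Hr <- matrix(runif(3 * 15, 0.1, 1), 3, 15)
  errRandom <- sum((X - Wr %*% Hr)^2)
  ## refit to recover H for the returned W (least squares, clipped)
  Hfit <- pmax(solve(crossprod(sc) + 1e-8 * diag(3), crossprod(sc, X)), 0)
  expect_lt(sum((X - sc %*% Hfit)^2), errRandom)
  expect_error(baselineReduce(X - 10, "nmf", 2L), "nonnegative")
})
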