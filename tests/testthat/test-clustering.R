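blobs <- function(n, k, sep = 6, d = 2L, seed = 1L) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * sep
  lab <- rep_len(seq_len(k), n)
  X <- centers[lab, , drop = FALSE] + matrix(rnorm(n * d, sd = 0.5), n, d)
  rownames(X) <- sprintf("s%03d", seq_len(n))
  list(X = X, lab = lab)
}

test_that("K-means closed forms: point masses and k = 1", {
  X <- rbind(matrix(rep(c(0, 0), 5), 5, 2, byrow = TRUE) +
               matrix(rnorm(10, sd = 0.01), 5, 2),
             matrix(rep(c(10, 10), 5), 5, 2, byrow = TRUE) +
               matrix(rnorm(10, sd = 0.01), 5, 2))
  rownames(X) <- sprintf("s%02d", 1:10)
  call <- kmeansCluster(X, 2L, seed = 1L)
  expect_identical(sort(as.integer(table(subtypeLabels(call)))), c(5L, 5L))
  withinScatter <- sum(vapply(1:2, function(g) {
    sub <- X[subtypeLabels(call) == g, ]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, 0))
  expect_equal(call@objective, withinScatter, tolerance = 1e-8)
  one <- kmeansCluster(X, 1L, seed = 1L)
  expect_equal(one@objective, sum(sweep(X, 2, colMeans(X))^2),
               tolerance = 1e-10)
  expect_equal(unname(one@centers[1, ]), unname(colMeans(X)))
})

test_that("K-means objective matches exhaustive 2-partition search", {
  set.seed(17)
  X <- matrix(rnorm(24), 12, 2)
  rownames(X) <- sprintf("s%02d", 1:12)
  call <- kmeansCluster(X, 2L, seed = 2L, nInit = 25L)
  expect_equal(call@objective, oracleBestJ2(X), tolerance = 1e-8)
})

test_that("labels are canonicalized by size and stable across seeds", {
  fx <- blobs(90, 3, seed = 4L)
  c1 <- kmeansCluster(fx$X, 3L, seed = 1L)
  c2 <- kmeansCluster(fx$X, 3L, seed = 999L)
  sizes <- as.integer(table(subtypeLabels(c1)))
  expect_true(all(diff(sizes) <= 0))              # descending
  agr <- clusteringAgreement(subtypeLabels(c1), subtypeLabels(c2))
  expect_gte(agr$ari, 0.95)
  ## determinism
  expect_identical(subtypeLabels(c1),
                   subtypeLabels(kmeansCluster(fx$X, 3L, seed = 1L)))
})

test_that("silhouette matches the direct per-point formula", {
  fx <- blobs(6, 2, sep = 4, seed = 8L)
  s <- silhouetteScore(fx$X, fx$lab)
  expect_equal(s, oracleSilhouette(fx$X, fx$lab), tolerance = 1e-12)
  expect_error(silhouetteScore(fx$X, rep(1, 6)), "single cluster")
  ## tight far-apart pairs approach 1
  far <- rbind(matrix(0.01 * rnorm(4), 2, 2),
               matrix(0.01 * rnorm(4) + 50, 2, 2))
  expect_gt(silhouetteScore(far, c(1, 1, 2, 2)), 0.99)
  ## random labels on one blob give near-zero silhouette
  set.seed(9)
  blob <- matrix(rnorm(200), 100, 2)
  expect_lt(abs(silhouetteScore(blob, sample(1:2, 100, TRUE))), 0.08)
})

test_that("CH matches a hand dispersion ratio; CH/DB move with separation", {
  fx <- blobs(40, 2, sep = 5, seed = 3L)
  d <- clusteringDiagnostics(fx$X, fx$lab)
  n <- 40; k <- 2
  grand <- colMeans(fx$X)
  B <- sum(vapply(1:2, function(g) {
    sub <- fx$X[fx$lab == g, ]
    nrow(sub) * sum((colMeans(sub) - grand)^2)
  }, 0))
  W <- sum(vapply(1:2, function(g) {
    sub <- fx$X[fx$lab == g, ]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, 0))
  expect_equal(d$CH, (B / (k - 1)) / (W / (n - k)), tolerance = 1e-10)
  near <- blobs(40, 2, sep = 1, seed = 3L)
  dNear <- clusteringDiagnostics(near$X, near$lab)
  expect_gt(d$CH, dNear$CH)
  expect_lt(d$DB, dNear$DB)
})

test_that("GMM-BIC recovers the true component count on separated blobs", {
  wins <- vapply(1:10, function(s) {
    fx <- blobs(120, 3, sep = 5, seed = s)
    bics <- vapply(2:4, function(k) {
      call <- kmeansCluster(fx$X, k, seed = s)
      clusteringDiagnostics(fx$X, subtypeLabels(call), seed = s)$BIC
    }, 0)
    which.min(bics) == 2L   # k = 3
  }, TRUE)
  expect_gte(mean(wins), 0.8)
})

test_that("k selection balances silhouette and survival separation", {
  ## three latent subtypes with distinct hazards -> k = 3
  picks <- vapply(1:5, function(s) {
    fx <- blobs(150, 3, sep = 5, seed = s)
    set.seed(s + 500)
    tt <- rexp(150, rate = c(0.002, 0.008, 0.03)[fx$lab])
    surv <- data.frame(sample = rownames(fx$X), time = tt,
                       event = rep(1L, 150))
    call <- selectNumClusters(fx$X, surv, seed = s)
    call@k
  }, 0L)
  expect_gte(mean(picks == 3L), 0.8)
  ## identical hazards: geometry alone decides, k = 2 on 2 blobs
  fx2 <- blobs(100, 2, sep = 6, seed = 7L)
  set.seed(7)
  surv2 <- data.frame(sample = rownames(fx2$X),
                      time = rexp(100, 0.01), event = 1L)
  call2 <- selectNumClusters(fx2$X, surv2, seed = 7L)
  expect_identical(call2@k, 2L)
  expect_identical(nrow(call2@diagnostics), 4L)
  ## singleton k range
  call3 <- selectNumClusters(fx2$X, surv2, kRange = 2L, seed = 1L)
  expect_identical(call3@k, 2L)
  expect_identical(nrow(call3@diagnostics), 1L)
})

test_that("selection is deterministic and degrades gracefully without events", {
  fx <- blobs(60, 2, sep = 6, seed = 2L)
  surv <- data.frame(sample = rownames(fx$X), time = rexp(60, 0.01),
                     event = 0L)
  expect_warning(call <- selectNumClusters(fx$X, surv, seed = 3L),
                 "degenerate")
  expect_identical(call@k, 2L)   # max silhouette fallback
  surv$event <- 1L
  a <- selectNumClusters(fx$X, surv, seed = 5L)
  b <- selectNumClusters(fx$X, surv, seed = 5L)
  expect_identical(subtypeLabels(a), subtypeLabels(b))
  expect_identical(a@diagnostics, b@diagnostics)
})
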