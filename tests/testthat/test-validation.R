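test_that("classifier matrix concatenates top-variance features per layer", {
  sim <- smallCohort(seed = 2L)
  Z <- buildClassifierMatrix(sim$cohort, nPerLayer = 20L)
  expect_identical(ncol(Z), 60L)
  expect_identical(rownames(Z), sampleIDs(sim$cohort))
  expect_true(all(grepl("^(rna|methylation|mirna)\\.", colnames(Z))))
  ## short layer contributes everything it has, with a warning
  expect_warning(Zbig <- buildClassifierMatrix(sim$cohort,
                                               nPerLayer = 50L),
                 "keeping all")
  expect_identical(ncol(Zbig), 50L + 40L + 30L)
  ## column set is invariant to sample order
  layers <- cohortLayers(sim$cohort)
  set.seed(3); shuf <- sample(length(sampleIDs(sim$cohort)))
  co2 <- alignCohort(lapply(layers, function(l)
    OmicsLayer(as.matrix(l)[shuf, ], layerKind(l))),
    survivalData(sim$cohort))
  expect_identical(colnames(buildClassifierMatrix(co2, nPerLayer = 20L)),
                   colnames(Z))
})

test_that("SVM achieves perfect accuracy on linearly separable pseudo-labels", {
  set.seed(5)
  n <- 90
  lab <- rep(1:3, each = 30)
  X <- matrix(rnorm(n * 6, sd = 0.3), n, 6) +
    cbind(outer(lab == 1, rep(4, 2)), outer(lab == 2, rep(4, 2)),
          outer(lab == 3, rep(4, 2)))
  rownames(X) <- sprintf("s%03d", 1:n)
  rep0 <- trainValidateSVM(X, lab, seed = 1L)
  expect_equal(rep0$accuracy, 1)
  expect_setequal(c(rep0$trainIdx, rep0$testIdx), seq_len(n))
  expect_length(intersect(rep0$trainIdx, rep0$testIdx), 0L)
  ## identical seed reproduces split and report
  rep1 <- trainValidateSVM(X, lab, seed = 1L)
  expect_identical(rep0$trainIdx, rep1$trainIdx)
  expect_identical(rep0$predicted, rep1$predicted)
  expect_identical(rep0$best, rep1$best)
})

test_that("shuffled labels drop accuracy to about the majority rate", {
  set.seed(6)
  n <- 120
  lab <- rep(1:2, each = 60)
  X <- matrix(rnorm(n * 5, sd = 0.3), n, 5) + outer(lab == 1, rep(3, 5))
  rownames(X) <- sprintf("s%03d", 1:n)
  shuffled <- sample(lab)
  repS <- trainValidateSVM(X, shuffled, seed = 2L)
  expect_lt(repS$accuracy, 0.75)
  repT <- trainValidateSVM(X, lab, seed = 2L)
  expect_gt(repT$accuracy, repS$accuracy)
})

test_that("chi-square association matches hand values and chisq.test", {
  ## perfectly proportional table: no association
  lab <- rep(c("k1", "k2"), each = 20)
  cov0 <- rep(c("A", "B"), times = 20)
  r0 <- chiSquareAssociation(lab, cov0)
  expect_equal(r0$chisq, 0, tolerance = 1e-12)
  expect_equal(r0$cramersV, 0)
  ## 2x2 diagonal: chi2 = n, V = 1
  lab1 <- rep(c("k1", "k2"), each = 10)
  cov1 <- rep(c("A", "B"), each = 10)
  r1 <- chiSquareAssociation(lab1, cov1)
  expect_equal(r1$chisq, 20, tolerance = 1e-12)
  expect_equal(r1$cramersV, 1, tolerance = 1e-12)
  expect_identical(r1$df, 1L)
  ## random table against the direct cell loop and chisq.test
  set.seed(7)
  labR <- sample(c("k1", "k2", "k3"), 200, TRUE)
  covR <- sample(c("I", "II", "III", "IV"), 200, TRUE)
  rR <- chiSquareAssociation(labR, covR)
  expect_equal(rR$chisq, oracleChisq(table(labR, covR)), tolerance = 1e-9)
  ref <- suppressWarnings(stats::chisq.test(table(labR, covR),
                                            correct = FALSE))
  expect_equal(rR$chisq, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(rR$p, unname(ref$p.value), tolerance = 1e-9)
  ## chi-square is invariant to relabeling rows/columns
  rPerm <- chiSquareAssociation(
    c(k1 = "x", k2 = "y", k3 = "z")[labR],
    c(I = "d", II = "c", III = "b", IV = "a")[covR])
  expect_equal(rPerm$chisq, rR$chisq, tolerance = 1e-12)
  ## missing covariate values are excluded, not coerced
  covM <- covR; covM[1:50] <- NA
  rM <- chiSquareAssociation(labR, covM)
  expect_identical(rM$n, 150L)
})

test_that("BH adjustment equals the hand step-up computation", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(fdrAdjust(p), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdrAdjust(0.2), 0.2)
  expect_equal(fdrAdjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(10)
  p2 <- runif(30)
  expect_true(all(fdrAdjust(p2) >= p2))  # adjusted never below raw
})

test_that("ARI/NMI: identity, renaming invariance, null expectation", {
  a <- rep(1:3, each = 10)
  r <- clusteringAgreement(a, a)
  expect_equal(r$ari, 1)
  expect_equal(r$nmi, 1)
  renamed <- c("z", "x", "y")[a]
  r2 <- clusteringAgreement(a, renamed)
  expect_equal(r2$ari, 1)
  expect_equal(r2$nmi, 1)
  ## matches the independent contingency-formula oracle and mclust
  set.seed(8)
  b <- sample(1:3, 30, TRUE)
  r3 <- clusteringAgreement(a, b)
  expect_equal(r3$ari, oracleARI(a, b), tolerance = 1e-12)
  expect_equal(r3$ari, mclust::adjustedRandIndex(a, b), tolerance = 1e-9)
  expect_gte(r3$nmi, 0); expect_lte(r3$nmi, 1)
  ## independent labelings: mean ARI near zero
  set.seed(9)
  aris <- vapply(1:100, function(i) {
    clusteringAgreement(sample(1:3, 200, TRUE),
                        sample(1:4, 200, TRUE))$ari
  }, 0)
  expect_gt(mean(aris), -0.02)
  expect_lt(mean(aris), 0.02)
})
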