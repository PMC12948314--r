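## Shared fixtures and independent oracle implementations.  Oracles are
## deliberately naive (loops, enumerations) and never call the package
## functions they check.

tinyLayer <- function(n = 6L, p = 4L, seed = 1L, kind = "rna") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  OmicsLayer(m, kind)
}

tinySurvival <- function(n = 6L, seed = 1L, censorFrac = 0.3) {
  set.seed(seed)
  data.frame(sample = sprintf("s%02d", seq_len(n)),
             time = rexp(n, 0.01),
             event = as.integer(runif(n) > censorFrac),
             stringsAsFactors = FALSE)
}

smallCohort <- function(seed = 1L, n = 120L) {
  generateCohort(simulationConfig(
    nSamples = n,
    featureCounts = c(rna = 60L, methylation = 40L, mirna = 30L),
    informativeCounts = c(rna = 20L, methylation = 12L, mirna = 10L),
    seed = seed))
}

## ---- independent oracles -------------------------------------------------

## geometric-mean correlation score, plain loops
oracleGeomMeanRho <- function(m) {
  cm <- abs(cor(m))
  n <- ncol(m)
  vapply(seq_len(n), function(i) prod(cm[i, ])^(1 / n), 0)
}

## silhouette by direct per-point evaluation
oracleSilhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

## exhaustive best 2-partition K-means objective
oracleBestJ2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in seq_len(2^(n - 1L) - 1L)) {
    lab <- as.integer(intToBits(code))[seq_len(n)]
    J <- 0
    for (g in 0:1) {
      sub <- X[lab == g, , drop = FALSE]
      J <- J + sum(sweep(sub, 2L, colMeans(sub), "-")^2)
    }
    best <- min(best, J)
  }
  best
}

## log-rank O/E/V accumulation with explicit loops (2 groups)
oracleLogrank2 <- function(time, event, group) {
  O1 <- E1 <- V1 <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V1 <- V1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(Z = (O1 - E1) / sqrt(V1), O1 = O1, E1 = E1, V1 = V1)
}

## concordance by explicit pair loops
oracleCindex <- function(risk, time, event, harrell = TRUE) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && (!harrell || event[i] == 1)) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

## chi-square by direct cell loop
oracleChisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

## ARI from the contingency-table formula, independent loops
oracleARI <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); sa <- sum(ch2(rowSums(tab)))
  sb <- sum(ch2(colSums(tab))); expct <- sa * sb / ch2(sum(tab))
  (sij - expct) / ((sa + sb) / 2 - expct)
}

## ---- shared benchmark runs (cached across test files) --------------------

.benchCache <- new.env(parent = emptyenv())

benchmarkRun <- function(seed, variant = "full") {
  key <- paste0(variant, "_", seed)
  if (!is.null(.benchCache[[key]])) return(.benchCache[[key]])
  sim <- generateCohort(simulationConfig(seed = seed))
  bm <- standardBenchmark(seed, classifier = FALSE)
  cfg <- bm$pipeConfig
  cfg$variant <- variant
  rep <- runPipeline(sim$cohort, cfg, referenceLabels = sim$truth$subtype)
  out <- list(report = rep, truth = sim$truth)
  .benchCache[[key]] <- out
  out
}
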