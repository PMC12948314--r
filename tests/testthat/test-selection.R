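## Survival-association filtering of latent features.

simDriver <- function(seed, n = 300L, pNoise = 20L, beta = 1) {
  set.seed(seed)
  driver <- rnorm(n)
  X <- cbind(driver = driver,
             matrix(rnorm(n * pNoise), n, pNoise,
                    dimnames = list(NULL, paste0("noise", seq_len(pNoise)))))
  rownames(X) <- sprintf("s%03d", seq_len(n))
  tTrue <- rexp(n, rate = 0.01 * exp(beta * driver))
  cens <- runif(n, 0, quantile(tTrue, 0.9) * 2)
  data <- data.frame(sample = rownames(X), time = pmin(tTrue, cens),
                     event = as.integer(tTrue <= cens))
  list(X = X, surv = data, driver = driver)
}

test_that("LASSO retains a true hazard driver among noise features", {
  hits <- vapply(1:6, function(s) {
    fx <- simDriver(s)
    sel <- lassoSelect(fx$X, fx$surv, seed = s)
    "driver" %in% sel$features
  }, TRUE)
  expect_gte(mean(hits), 5 / 6)
})

test_that("LASSO selects nearly nothing when survival is independent", {
  sizes <- vapply(1:6, function(s) {
    fx <- simDriver(s, beta = 0)
    sel <- lassoSelect(fx$X, fx$surv, seed = s)
    length(sel$features)
  }, 0L)
  expect_lte(median(sizes), 2)
})

test_that("L1 concentrates a duplicated column's weight on one member", {
  ## with exact duplicates the L1 optimum only pins down the coefficient
  ## sum; coordinate descent concentrates it on one column, leaving at
  ## most a negligible remainder on the copy
  fx <- simDriver(3L)
  X2 <- cbind(fx$X, driver_copy = fx$X[, "driver"])
  sel <- lassoSelect(X2, fx$surv, seed = 3L)
  pair <- abs(sel$coefficients[c("driver", "driver_copy")])
  pair[is.na(pair)] <- 0
  expect_gt(max(pair), 0)
  expect_lt(min(pair), 0.05 * max(pair))
})

test_that("zero events is a hard error", {
  fx <- simDriver(1L)
  fx$surv$event <- 0L
  expect_error(lassoSelect(fx$X, fx$surv), "events")
})

test_that("univariate Cox filter keeps a positive control and reports HR", {
  fx <- simDriver(2L)
  out <- coxUnivariateFilter(fx$X, c("driver", "noise1"), fx$surv)
  expect_identical(attr(out, "alpha"), 0.05)
  drv <- out[out$feature == "driver", ]
  expect_lt(drv$p, 1e-6)
  expect_true(drv$retained)
  expect_gt(drv$hazardRatio, 1)
  ## empty candidate list is fine
  empty <- coxUnivariateFilter(fx$X, character(), fx$surv)
  expect_identical(nrow(empty), 0L)
})

test_that("null features are retained at roughly the alpha rate", {
  ## 60 cohorts x 10 null features; binomial band around 0.05
  set.seed(20)
  rates <- vapply(1:60, function(s) {
    fx <- simDriver(s + 1000L, n = 100L, pNoise = 9L, beta = 0)
    out <- coxUnivariateFilter(fx$X, colnames(fx$X), fx$surv)
    mean(out$retained)
  }, 0)
  se <- sqrt(0.05 * 0.95 / (60 * 10))
  expect_lt(abs(mean(rates) - 0.05), 4 * se + 0.005)
})

test_that("lowering alpha never enlarges the retained set", {
  fx <- simDriver(4L)
  cand <- colnames(fx$X)
  out10 <- coxUnivariateFilter(fx$X, cand, fx$surv, alpha = 0.10)
  out05 <- coxUnivariateFilter(fx$X, cand, fx$surv, alpha = 0.05)
  out01 <- coxUnivariateFilter(fx$X, cand, fx$surv, alpha = 0.01)
  keep <- function(o) o$feature[o$retained]
  expect_true(all(keep(out05) %in% keep(out10)))
  expect_true(all(keep(out01) %in% keep(out05)))
})

test_that("the median-split log-rank screening variant runs", {
  fx <- simDriver(5L)
  out <- coxUnivariateFilter(fx$X, c("driver", "noise2"), fx$surv,
                             method = "logrank_median")
  expect_lt(out$p[out$feature == "driver"], 0.01)
})

test_that("combineSelected concatenates layer blocks deterministically", {
  set.seed(6)
  mk <- function(p, pre) {
    m <- matrix(rnorm(10 * p), 10, p,
                dimnames = list(sprintf("s%02d", 1:10),
                                paste0("z", seq_len(p))))
    m
  }
  a <- mk(5); b <- mk(4); c0 <- mk(3)
  per <- list(rna = list(latent = a, selected = c("z1", "z3", "z5")),
              meth = list(latent = b, selected = character()),
              mirna = list(latent = c0, selected = c("z2", "z3")))
  out <- combineSelected(per)
  expect_identical(colnames(out),
                   c("rna.z1", "rna.z3", "rna.z5", "mirna.z2", "mirna.z3"))
  expect_identical(out, combineSelected(per))  # stable under re-run
  single <- combineSelected(per["rna"])
  expect_equal(unname(single), unname(a[, c(1, 3, 5)]))
  none <- list(rna = list(latent = a, selected = character()))
  expect_error(combineSelected(none), "relaxing")
})
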