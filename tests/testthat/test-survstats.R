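test_that("Kaplan-Meier equals the empirical survival without censoring", {
  surv <- data.frame(sample = paste0("s", 1:3), time = c(1, 2, 3),
                     event = 1L)
  km <- kaplanMeier(surv)
  expect_equal(km$survival, c(1, 2/3, 1/3, 0))
  allCens <- data.frame(sample = paste0("s", 1:4), time = 1:4, event = 0L)
  expect_true(all(kaplanMeier(allCens)$survival == 1))
})

test_that("Kaplan-Meier matches a hand product-limit table with censoring", {
  ## times 1,2+,3,4+,5,6 (+: censored)
  surv <- data.frame(sample = paste0("s", 1:6),
                     time = c(1, 2, 3, 4, 5, 6),
                     event = c(1, 0, 1, 0, 1, 1))
  km <- kaplanMeier(surv)
  ## hand: S(1)=5/6; S(3)=5/6*3/4; S(5)=5/6*3/4*1/2; S(6)=0
  expect_equal(km$survival[km$time %in% c(1, 3, 5, 6)],
               c(5/6, 5/6 * 3/4, 5/6 * 3/4 * 1/2, 0), tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 1e-12))
  ## cross-check against the survival package estimator
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv)
  expect_equal(km$survival[km$time %in% sf$time & km$time %in%
                             surv$time[surv$event == 1]],
               sf$surv[sf$n.event > 0], tolerance = 1e-12)
})

test_that("log-rank: symmetry, tabular oracle and survdiff agreement", {
  ## two copies of identical data -> no difference signal
  base <- data.frame(sample = paste0("s", 1:8),
                     time = c(1, 2, 3, 4, 1, 2, 3, 4),
                     event = rep(1L, 8))
  r <- logrankTest(base, rep(c("a", "b"), each = 4))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
  ## group A fails entirely before group B: oracle accumulation
  surv <- data.frame(sample = paste0("s", 1:8),
                     time = c(1, 2, 3, 4, 10, 11, 12, 13),
                     event = 1L)
  grp <- rep(1:0, each = 4)
  r2 <- logrankTest(surv, grp)
  orc <- oracleLogrank2(surv$time, surv$event, grp)
  ## our group "0" sorts first; oracle tracks group 1 -> compare |Z| and O/E
  expect_equal(abs(r2$statistic), abs(orc$Z), tolerance = 1e-9)
  expect_equal(r2$table$O[r2$table$group == "1"], orc$O1)
  expect_equal(r2$table$E[r2$table$group == "1"], orc$E1, tolerance = 1e-9)
  expect_equal(r2$table$V[r2$table$group == "1"], orc$V1, tolerance = 1e-9)
  ## O - E sums to zero across groups
  expect_lt(abs(sum(r2$table$O - r2$table$E)), 1e-9)
  ## chisq agrees with survival::survdiff on a random censored fixture
  set.seed(21)
  n <- 40
  fx <- data.frame(sample = sprintf("s%02d", 1:n),
                   time = rexp(n, 0.05), event = rbinom(n, 1, 0.7))
  g <- sample(c("x", "y", "z"), n, TRUE)
  mine <- logrankTest(fx, g)
  ref <- survival::survdiff(survival::Surv(time, event) ~ g, data = fx)
  expect_equal(mine$chisq, ref$chisq, tolerance = 1e-8)
  expect_identical(mine$df, 2L)
})

test_that("concordance index: closed forms and pair-loop oracle", {
  ## perfect anti-ordering: higher risk, earlier death
  surv <- data.frame(sample = paste0("s", 1:5), time = 1:5, event = 1L)
  expect_equal(concordanceIndex(5:1, surv)$cindex, 1)
  ## constant risk scores 0.5 under Harrell ties
  expect_equal(concordanceIndex(rep(2, 5), surv)$cindex, 0.5)
  ## censored fixture vs exhaustive pair enumeration, both modes
  fx <- data.frame(sample = paste0("s", 1:5),
                   time = c(2, 5, 3, 8, 4), event = c(1, 1, 0, 1, 1))
  risk <- c(1.2, -0.5, 0.3, -1.1, 0.3)
  for (mode in c("harrell", "literal")) {
    mine <- concordanceIndex(risk, fx, mode = mode)
    expect_equal(mine$cindex,
                 oracleCindex(risk, fx$time, fx$event,
                              harrell = mode == "harrell"),
                 tolerance = 1e-12)
  }
  ## flipping the risk sign maps C to 1 - C (no ties in risk)
  set.seed(31)
  fx2 <- data.frame(sample = paste0("s", 1:30), time = rexp(30, 0.1),
                    event = rbinom(30, 1, 0.8))
  r2 <- rnorm(30)
  c1 <- concordanceIndex(r2, fx2)$cindex
  c2 <- concordanceIndex(-r2, fx2)$cindex
  expect_equal(c1 + c2, 1, tolerance = 1e-12)
  ## agreement with survival::concordance on untied data
  ref <- survival::concordance(survival::Surv(time, event) ~ r2,
                               data = fx2, reverse = TRUE)
  expect_equal(c1, as.numeric(ref$concordance), tolerance = 1e-9)
})

test_that("bootstrap CI: degenerate statistic, shrinking width, seeding", {
  cc <- bootstrapCI(function(idx) 42, nSamples = 50, nBoot = 100,
                    seed = 1L)
  expect_equal(c(cc$lower, cc$upper), c(42, 42))
  set.seed(2)
  mk <- function(n) {
    r <- rnorm(n)
    s <- data.frame(time = rexp(n, 0.05 * exp(r)), event = 1L)
    function(idx) concordanceIndex(r[idx], s[idx, , drop = FALSE])$cindex
  }
  f100 <- mk(100); f400 <- mk(400)
  ci100 <- bootstrapCI(f100, 100, nBoot = 150, seed = 3L)
  ci400 <- bootstrapCI(f400, 400, nBoot = 150, seed = 3L)
  expect_lt(ci400$upper - ci400$lower, ci100$upper - ci100$lower)
  rep1 <- bootstrapCI(f100, 100, nBoot = 100, seed = 9L)
  rep2 <- bootstrapCI(f100, 100, nBoot = 100, seed = 9L)
  expect_identical(rep1$replicates, rep2$replicates)
  expect_error(
    bootstrapCI(function(idx) stop("nope"), 20, nBoot = 100, seed = 1L),
    "10%")
})

test_that("Cox risk score recovers generative concordance; null gives 0.5", {
  set.seed(41)
  n <- 300
  driver <- rnorm(n)
  tt <- rexp(n, rate = 0.01 * exp(driver))
  cens <- runif(n, 0, quantile(tt, 0.9) * 2)
  surv <- data.frame(sample = sprintf("s%03d", 1:n),
                     time = pmin(tt, cens),
                     event = as.integer(tt <= cens))
  X <- cbind(z1 = driver)
  rownames(X) <- surv$sample
  risk <- riskScoreForCindex(X, surv)
  cHat <- concordanceIndex(risk, surv)$cindex
  cTrue <- concordanceIndex(driver, surv)$cindex
  expect_lt(abs(cHat - cTrue), 0.03)
  ## independent feature: C near 0.5
  Xnull <- cbind(z1 = rnorm(n)); rownames(Xnull) <- surv$sample
  cNull <- concordanceIndex(riskScoreForCindex(Xnull, surv), surv)$cindex
  expect_lt(abs(cNull - 0.5), 0.05)
  ## deterministic
  expect_identical(risk, riskScoreForCindex(X, surv))
})
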