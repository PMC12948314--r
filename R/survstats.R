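## Survival statistics implemented from their defining formulas:
## Kaplan-Meier product-limit curves, the (k-sample) log-rank test with
## explicit O/E/V bookkeeping, the concordance index in both a literal
## all-pairs form and the censoring-aware Harrell form, and percentile
## bootstrap confidence intervals.

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator: at each distinct event time `t` within a
#' group, the survival estimate is multiplied by `1 - d_t / n_t` where
#' `d_t` is the number of events and `n_t` the number at risk; censored
#' subjects leave the risk set without an event step.  With no censoring
#' the curve equals the empirical survival function.
#'
#' @param survival data.frame with `time` and `event`.
#' @param labels group label per sample (a single group if omitted).
#' @return data.frame with columns `group`, `time`, `nRisk`, `nEvent`,
#'   `nCensor`, `survival`; each group starts at `time = 0`,
#'   `survival = 1`.
#' @export
kaplanMeier <- function(survival, labels = NULL) {
  if (is.null(labels)) labels <- rep("all", nrow(survival))
  labels <- as.character(labels)
  if (length(labels) != nrow(survival))
    stop("labels length must match the survival table")
  out <- lapply(sort(unique(labels)), function(g) {
    idx <- labels == g
    if (!any(idx)) stop("group '", g, "' has zero subjects")
    tt <- survival$time[idx]; ev <- survival$event[idx]
    times <- sort(unique(tt))
    n <- length(tt)
    S <- 1
    rows <- data.frame(group = g, time = 0, nRisk = n, nEvent = 0L,
                       nCensor = 0L, survival = 1,
                       stringsAsFactors = FALSE)
    for (t in times) {
      atRisk <- sum(tt >= t)
      d <- sum(tt == t & ev == 1)
      c0 <- sum(tt == t & ev == 0)
      if (d > 0) S <- S * (1 - d / atRisk)
      rows <- rbind(rows, data.frame(group = g, time = t, nRisk = atRisk,
                                     nEvent = d, nCensor = c0,
                                     survival = S,
                                     stringsAsFactors = FALSE))
    }
    rows
  })
  do.call(rbind, out)
}

#' Log-rank test across survival groups
#'
#' At every distinct event time the observed events per group are compared
#' with the expectation under the null hypothesis that all groups share
#' one hazard, accumulating observed (`O`), expected (`E`) and the
#' hypergeometric (co)variance over the shared risk set.  For two groups
#' the statistic is `Z = (O_1 - E_1) / sqrt(V_1)` with a two-sided normal
#' p-value (equivalently `Z^2` against chi-square with 1 df); for `k > 2`
#' groups the chi-square generalization with `k - 1` degrees of freedom is
#' used.  The per-group `O - E` sum to zero by construction.
#'
#' @param survival data.frame with `time` and `event`.
#' @param labels group label per sample, >= 2 groups, >= 1 event overall.
#' @return list with `statistic` (`Z` for 2 groups, chi-square for more),
#'   `chisq`, `df`, `p` and `table` (per-group n, O, E, V).
#' @export
logrankTest <- function(survival, labels) {
  labels <- as.character(labels)
  if (length(labels) != nrow(survival))
    stop("labels length must match the survival table")
  groups <- sort(unique(labels))
  k <- length(groups)
  if (k < 2L) stop("log-rank test needs at least 2 groups")
  if (sum(survival$event) == 0) stop("no events observed")
  tt <- survival$time; ev <- survival$event
  gi <- match(labels, groups)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(tt[ev == 1]))) {
    at <- tt >= t
    n <- sum(at)
    nj <- vapply(seq_len(k), function(g) sum(at & gi == g), 0)
    d <- sum(tt == t & ev == 1)
    dj <- vapply(seq_len(k), function(g) sum(tt == t & ev == 1 & gi == g), 0)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      frac <- nj / n
      V <- V + d * (n - d) / (n - 1) *
        (diag(frac, nrow = k) - tcrossprod(frac))
    }
  }
  if (k == 2L) {
    if (V[1L, 1L] <= 0) stop("degenerate log-rank variance")
    Z <- (O[1L] - E[1L]) / sqrt(V[1L, 1L])
    chisq <- Z^2
    df <- 1L
    p <- 2 * pnorm(-abs(Z))
    statistic <- Z
  } else {
    idx <- seq_len(k - 1L)
    Vsub <- V[idx, idx, drop = FALSE]
    qr0 <- qr(Vsub)
    if (qr0$rank < k - 1L) stop("degenerate log-rank covariance")
    u <- (O - E)[idx]
    chisq <- as.numeric(t(u) %*% solve(Vsub, u))
    df <- k - 1L
    p <- pchisq(chisq, df, lower.tail = FALSE)
    statistic <- chisq
  }
  list(statistic = statistic, chisq = chisq, df = df, p = p,
       table = data.frame(group = groups,
                          n = as.integer(table(factor(labels,
                                                      levels = groups))),
                          O = O, E = E, V = diag(V)))
}

#' Concordance index of a risk score
#'
#' `mode = "harrell"` (default): pairs are comparable only when the
#' earlier observed time is an event (`T_i < T_j`, `event_i = 1`); a pair
#' is concordant when the earlier-failing subject has the higher risk, and
#' tied risks score 0.5.  `mode = "literal"` scores
#' `C = sum I(h_i > h_j) I(T_i < T_j) / sum I(T_i < T_j)` over all ordered
#' pairs, ignoring censoring (the formula-faithful variant; tied risks
#' also score 0.5).
#'
#' @param risk numeric risk score per sample (higher = worse prognosis).
#' @param survival data.frame with `time` and `event`.
#' @param mode `"harrell"` or `"literal"`.
#' @return list with `cindex`, `comparablePairs`, `concordant`,
#'   `tiedRisk`, `mode`.
#' @export
concordanceIndex <- function(risk, survival,
                             mode = c("harrell", "literal")) {
  mode <- match.arg(mode)
  stopifnot(length(risk) == nrow(survival), all(is.finite(risk)))
  tt <- survival$time; ev <- survival$event
  earlier <- outer(tt, tt, "<")                 # [i, j]: T_i < T_j
  comp <- if (mode == "harrell") earlier & (ev == 1) else earlier
  nComp <- sum(comp)
  if (nComp == 0) stop("no comparable pairs")
  hi <- outer(risk, risk, ">")
  te <- outer(risk, risk, "==")
  conc <- sum(hi & comp)
  ties <- sum(te & comp)
  list(cindex = (conc + 0.5 * ties) / nComp, comparablePairs = nComp,
       concordant = conc, tiedRisk = ties, mode = mode)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples sample indices with replacement `nBoot` times, evaluates
#' `statistic(indices)` on each replicate, and returns the percentile
#' interval at the requested level.  Replicates on which the statistic
#' fails (error or non-finite value) are discarded; more than 10%
#' failures is a hard error.
#'
#' @param statistic function taking an integer index vector (a resample of
#'   `1..nSamples`) and returning one number.
#' @param nSamples cohort size to resample from.
#' @param nBoot number of bootstrap replicates (>= 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `lower`, `upper`, `level`, `replicates` (the kept
#'   bootstrap values), `nFailed`, `seed`.
#' @export
bootstrapCI <- function(statistic, nSamples, nBoot = 1000L, level = 0.95,
                        seed = 1L) {
  stopifnot(nBoot >= 100L, level > 0, level < 1)
  set.seed(seed)
  vals <- numeric(nBoot)
  failed <- 0L
  for (b in seq_len(nBoot)) {
    idx <- sample.int(nSamples, nSamples, replace = TRUE)
    v <- tryCatch(statistic(idx), error = function(e) NA_real_)
    if (!is.finite(v)) { failed <- failed + 1L; v <- NA_real_ }
    vals[b] <- v
  }
  if (failed > 0.1 * nBoot)
    stop("statistic failed on more than 10% of bootstrap resamples")
  keep <- vals[is.finite(vals)]
  qs <- quantile(keep, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  list(lower = qs[1L], upper = qs[2L], level = level, replicates = keep,
       nFailed = failed, seed = seed)
}

#' Cox linear-predictor risk score for concordance evaluation
#'
#' Fits a multivariate Cox proportional-hazards model on the selected
#' latent features and returns its linear predictor as the per-sample risk
#' score.  If the fit fails or diverges, a ridge-stabilized fit
#' (L2-penalized Cox via glmnet at a small penalty) is used instead, with
#' a warning.
#'
#' @param selected samples x features matrix of survival-selected latent
#'   features.
#' @param survival data.frame with `time` and `event`.
#' @return Numeric risk score per sample (higher = higher hazard).
#' @export
riskScoreForCindex <- function(selected, survival) {
  X <- as.matrix(selected)
  stopifnot(ncol(X) >= 1L, nrow(X) == nrow(survival))
  tt <- survival$time
  if (any(tt <= 0)) tt[tt <= 0] <- min(tt[tt > 0]) / 2
  y <- survival::Surv(tt, survival$event)
  fit <- tryCatch({
    f <- survival::coxph(y ~ X,
                         control = survival::coxph.control(iter.max = 50))
    if (any(!is.finite(coef(f)))) stop("diverged")
    f
  }, error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    lp <- as.numeric(X %*% coef(fit))
  } else {
    warning("Cox fit did not converge; using a ridge-stabilized fit")
    rf <- glmnet::glmnet(X, y, family = "cox", alpha = 0, lambda = 0.01)
    lp <- as.numeric(predict(rf, newx = X, s = 0.01, type = "link"))
  }
  names(lp) <- rownames(X)
  lp
}
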