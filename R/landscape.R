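# Island geometry, sex-ratio chi-square tests, VIF screening, the dAIc
# multiple regression with backward stepwise selection under AICc, and
# two-predictor variance partitioning.

#' Island shape metrics from area and perimeter
#'
#' Areas are supplied in hectares (the survey convention) and converted to
#' square metres internally (1 ha = 1e4 m2). The perimeter/area ratio
#' `PAR = P / A` (1/m) indexes the relative amount of core habitat; the shape
#' index `SI = P / (2 * sqrt(pi * A))` is 1 for a circle and grows with shape
#' complexity. An SI below 1 is geometrically impossible for a simple closed
#' shape and is flagged with a warning.
#'
#' @param area_ha island area in hectares (> 0); vectorized.
#' @param perimeter_m island perimeter in metres (> 0).
#' @return data.frame with columns `par` (1/m) and `si` (dimensionless).
#' @export
shape_metrics <- function(area_ha, perimeter_m) {
  if (any(area_ha <= 0) || any(perimeter_m <= 0))
    stop("area and perimeter must be positive")
  a_m2 <- area_ha * 1e4
  par <- perimeter_m / a_m2
  si <- perimeter_m / (2 * sqrt(pi * a_m2))
  if (any(si < 1 - 1e-9))
    warning("SI < 1: inconsistent geometry (perimeter below the equal-area circle)")
  data.frame(par = par, si = si)
}

#' Chi-square test of an even sex ratio
#'
#' Tests the male/female counts on an island against the 1:1 expectation with
#' a 1-df goodness-of-fit chi-square, no continuity correction:
#' `chi2 = (m - f)^2 / (m + f)`.
#'
#' @param n_male,n_female counts (vectorized; `n_male + n_female >= 1`).
#' @return data.frame with columns `n_male`, `n_female`, `chi2`, `p`.
#' @export
sex_ratio_chi2 <- function(n_male, n_female) {
  n <- n_male + n_female
  if (any(n < 1)) stop("need at least one individual")
  chi2 <- (n_male - n_female)^2 / n
  data.frame(n_male = n_male, n_female = n_female, chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the regression of predictor
#' `j` on all other predictors (with intercept). Predictors exceeding the
#' threshold (default 10) are flagged for exclusion before modelling; exact
#' collinearity yields an infinite VIF.
#'
#' @param design data.frame or matrix of >= 2 numeric predictors.
#' @param threshold VIF above which a predictor is flagged (default 10).
#' @return data.frame with columns `predictor`, `vif`, `flagged`.
#' @export
vif <- function(design, threshold = 10) {
  X <- as.data.frame(design)
  if (ncol(X) < 2L) stop("VIF needs at least two predictors")
  if (nrow(X) <= ncol(X) + 1L) stop("too few rows for VIF screening")
  v <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    # a perfect fit here is exact collinearity, reported as infinite VIF;
    # summary.lm's perfect-fit warning is expected in that case
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = names(X), vif = v, flagged = v > threshold,
             stringsAsFactors = FALSE)
}

# AICc with K = (number of regression coefficients incl. intercept) + 1 for
# the error variance: AICc = n log(RSS/n) + 2K + 2K(K+1)/(n-K-1)
aicc_from_rss <- function(rss, n, k_predictors) {
  K <- k_predictors + 2
  if (n - K - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Ordinary least squares fit with AICc
#'
#' Fits `y ~ X` by least squares (with intercept; `X` may have zero columns
#' for the intercept-only model) and reports the coefficient vector, R2, the
#' overall F statistic `[R2/k] / [(1-R2)/(n-k-1)]` with its p-value, and the
#' small-sample AICc with `K = k + 2` parameters (coefficients including the
#' intercept, plus the error variance).
#'
#' @param y numeric response.
#' @param X data.frame/matrix of predictors (0 or more columns).
#' @return list of class `model_fit`: `predictors`, `coefficients`, `r2`,
#'   `f`, `p`, `aicc`, `rss`, `n`, `k`, `lm` (the underlying fit).
#' @export
ols_fit <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1L) stop("n must exceed the number of predictors + 1")
  dat <- cbind(data.frame(.y = y), X)
  fit <- if (k == 0L) stats::lm(.y ~ 1, data = dat)
         else stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit)))
    stop("singular design: dependent columns ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  if (k > 0L && r2 < 1) {
    f <- (r2 / k) / ((1 - r2) / (n - k - 1))
    pf <- stats::pf(f, k, n - k - 1, lower.tail = FALSE)
  } else {
    f <- if (k > 0L) Inf else NA_real_
    pf <- if (k > 0L) 0 else NA_real_
  }
  structure(list(predictors = names(X), coefficients = stats::coef(fit),
                 r2 = r2, f = f, p = pf,
                 aicc = aicc_from_rss(rss, n, k), rss = rss, n = n, k = k,
                 lm = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("OLS fit:", if (x$k) paste(x$predictors, collapse = " + ") else "(intercept only)", "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  R2 = %.3f  F = %.3f (p = %.4g)  AICc = %.2f  n = %d\n",
              x$r2, x$f, x$p, x$aicc, x$n))
  invisible(x)
}

#' Backward stepwise selection under AICc
#'
#' Starting from the full set of (VIF-passing) predictors, repeatedly drops
#' the single predictor whose removal lowers AICc the most, stopping when no
#' removal lowers AICc. Predictors never re-enter. The full trace (one row per
#' accepted step, plus the starting model) is returned for audit.
#'
#' @param y numeric response (e.g. per-island dAIc).
#' @param X data.frame of candidate predictors.
#' @return list with `fit` (the selected [ols_fit()]) and `trace`
#'   (data.frame `step`, `dropped`, `k`, `aicc`).
#' @seealso [exhaustive_aicc()] for the all-subsets audit.
#' @export
backward_stepwise_aicc <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y)
  if (n - (ncol(X) + 2) - 1 <= 0)
    stop("n too small for the full model; pre-screen predictors first")
  current <- names(X)
  fit <- ols_fit(y, X[current])
  trace <- data.frame(step = 0L, dropped = "", k = fit$k, aicc = fit$aicc,
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(current) == 0L) break
    cand <- vapply(current, function(v)
      ols_fit(y, X[setdiff(current, v)])$aicc, numeric(1))
    best <- which.min(cand)
    if (cand[best] >= fit$aicc) break
    step <- step + 1L
    dropped <- current[best]
    current <- setdiff(current, dropped)
    fit <- ols_fit(y, X[current])
    trace <- rbind(trace, data.frame(step = step, dropped = dropped,
                                     k = fit$k, aicc = fit$aicc,
                                     stringsAsFactors = FALSE))
  }
  list(fit = fit, trace = trace)
}

#' Exhaustive all-subsets AICc search
#'
#' Fits every subset of the candidate predictors and returns the AICc-minimal
#' model; an audit companion to [backward_stepwise_aicc()].
#'
#' @inheritParams backward_stepwise_aicc
#' @return list with `fit` (best [ols_fit()]), `best` (character vector of
#'   retained predictors) and `table` (data.frame `subset`, `k`, `aicc`).
#' @export
exhaustive_aicc <- function(y, X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  subsets <- lapply(0:(2^p - 1), function(m) names(X)[bitwAnd(m, 2^(seq_len(p) - 1)) > 0])
  tab <- data.frame(subset = vapply(subsets, function(s)
    if (length(s)) paste(s, collapse = "+") else "(intercept)", character(1)),
    k = vapply(subsets, length, integer(1)),
    aicc = vapply(subsets, function(s) ols_fit(y, X[s])$aicc, numeric(1)),
    stringsAsFactors = FALSE)
  best <- subsets[[which.min(tab$aicc)]]
  list(fit = ols_fit(y, X[best]), best = best, table = tab)
}

#' Two-predictor variance partitioning
#'
#' Decomposes the full-model R2 of `y ~ x1 + x2` into the unique contribution
#' of each predictor and their shared fraction (commonality analysis):
#' `unique_1 = R2(x1,x2) - R2(x2)`, `unique_2 = R2(x1,x2) - R2(x1)`,
#' `shared = R2(x1) + R2(x2) - R2(x1,x2)`. The shared fraction can be negative
#' under suppression; it is reported as-is with a flag.
#'
#' @param y numeric response.
#' @param x1,x2 numeric predictors.
#' @return list with `unique_1`, `unique_2`, `shared`, `unexplained`,
#'   `r2_full`, `suppression` (logical).
#' @export
variance_partition <- function(y, x1, x2) {
  # aliased columns (e.g. x2 an exact copy of x1) are legitimate here: lm
  # drops the alias and the full-model R2 collapses to the single-predictor R2
  r2_1 <- summary(stats::lm(y ~ x1))$r.squared
  r2_2 <- summary(stats::lm(y ~ x2))$r.squared
  r2_12 <- summary(stats::lm(y ~ x1 + x2))$r.squared
  u1 <- r2_12 - r2_2
  u2 <- r2_12 - r2_1
  sh <- r2_1 + r2_2 - r2_12
  list(unique_1 = u1, unique_2 = u2, shared = sh,
       unexplained = 1 - r2_12, r2_full = r2_12, suppression = sh < 0)
}

#' Island-attribute summary aggregates
#'
#' Mean, sample standard deviation (n-1 denominator), minimum and maximum for
#' each island attribute. The sex ratio is computed per island as
#' `n_male / n_female` before aggregation (the per-island-ratio convention);
#' islands with zero sampled females have an undefined ratio and are excluded
#' from the SR summary with a warning.
#'
#' @param attrs data.frame with island attribute columns; any of `area_ha`,
#'   `isolation_m`, `par`, `si`, `breeding_sites`, `n_male`, `n_female` that
#'   are present are summarized.
#' @return data.frame with columns `attribute`, `mean`, `sd`, `min`, `max`.
#' @export
attribute_aggregates <- function(attrs) {
  if (nrow(attrs) < 2L) stop("need >= 2 islands")
  cols <- intersect(c("area_ha", "isolation_m", "par", "si", "breeding_sites"),
                    names(attrs))
  vals <- attrs[cols]
  if (all(c("n_male", "n_female") %in% names(attrs))) {
    sr <- attrs$n_male / attrs$n_female
    bad <- !is.finite(sr)
    if (any(bad)) {
      warning("sex ratio undefined (zero females) on: ",
              paste(attrs$island[bad], collapse = ", "))
      sr <- sr[!bad]
    }
    vals$sex_ratio <- NA_real_  # placeholder, replaced below
    vals <- vals[setdiff(names(vals), "sex_ratio")]
    extra <- list(sex_ratio = sr)
  } else extra <- list()
  agg <- lapply(names(vals), function(cn) {
    v <- vals[[cn]]
    data.frame(attribute = cn, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  agg <- c(agg, lapply(names(extra), function(cn) {
    v <- extra[[cn]]
    data.frame(attribute = cn, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
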