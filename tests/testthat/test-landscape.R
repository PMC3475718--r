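# geometry, sex-ratio chi-square, VIF, OLS/AICc, stepwise, partitioning

test_that("shape metrics recover closed forms and the surveyed geometry", {
  # circle of radius r: SI = 1
  r <- 123.4
  circ <- shape_metrics(pi * r^2 / 1e4, 2 * pi * r)
  expect_equal(circ$si, 1, tolerance = 1e-12)
  # unit square (A = 1 m2, P = 4 m): SI = 2/sqrt(pi)
  sq <- shape_metrics(1e-4, 4)
  expect_equal(sq$si, 2 / sqrt(pi), tolerance = 1e-12)
  expect_equal(sq$par, 4)
  # island 01: PAR recomputed from the published area and shape index
  s <- tkl_island_survey()
  g <- shape_metrics(s$area_ha[1], s$perimeter_m[1])
  expect_equal(round(g$par, 3), 0.013)
  expect_equal(g$si, s$si[1], tolerance = 1e-9)
  expect_error(shape_metrics(-1, 10), "positive")
  expect_warning(shape_metrics(1, 10), "SI < 1")
})

test_that("sex-ratio chi-square uses no continuity correction", {
  res <- sex_ratio_chi2(c(11, 8, 5), c(30, 8, 5))
  expect_equal(res$chi2[1], 8.804878, tolerance = 1e-6)
  expect_equal(res$chi2[2], 0)
  expect_equal(res$p[2], 1)
  expect_equal(res$chi2[3], 0)
  # cross-check against the base goodness-of-fit test
  ct <- chisq.test(c(11, 30), p = c(0.5, 0.5))
  expect_equal(res$chi2[1], unname(ct$statistic))
  expect_equal(res$p[1], ct$p.value)
  expect_error(sex_ratio_chi2(0, 0), "at least one")
})

test_that("VIF matches closed forms and flags exact collinearity", {
  set.seed(51)
  n <- 30
  x1 <- rnorm(n)
  e <- residuals(lm(rnorm(n) ~ x1))
  r <- 0.9
  x2 <- r * scale(x1)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
  v <- vif(data.frame(x1 = scale(x1)[, 1], x2 = x2))
  expect_equal(v$vif, rep(1 / (1 - r^2), 2), tolerance = 1e-8)
  # orthogonal centered predictors: VIF = 1
  v0 <- vif(data.frame(x1 = scale(x1)[, 1], x2 = scale(e)[, 1]))
  expect_equal(v0$vif, c(1, 1), tolerance = 1e-10)
  # duplicated column: infinite, flagged
  vd <- vif(data.frame(a = x1, b = x1))
  expect_true(all(is.infinite(vd$vif)))
  expect_true(all(vd$flagged))
  # agreement with the car package on a larger design
  X <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  y <- rowSums(X) + rnorm(n)
  fit <- lm(y ~ ., data = X)
  expect_equal(unname(vif(X)$vif), unname(car::vif(fit)), tolerance = 1e-8)
})

test_that("OLS fit matches the normal equations, F identity, and noiseless lines", {
  x <- 1:10
  f <- ols_fit(2 * x + 1, data.frame(x = x))
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-12)
  expect_equal(f$r2, 1)
  set.seed(52)
  X <- matrix(rnorm(14 * 3), 14, 3)
  y <- rnorm(14)
  f2 <- ols_fit(y, as.data.frame(X))
  beta <- solve(t(cbind(1, X)) %*% cbind(1, X), t(cbind(1, X)) %*% y)
  expect_equal(unname(f2$coefficients), as.numeric(beta), tolerance = 1e-8)
  expect_equal(f2$f, (f2$r2 / 3) / ((1 - f2$r2) / (14 - 3 - 1)), tolerance = 1e-10)
  # AICc closed form with K = k + 2
  K <- 5
  expect_equal(f2$aicc,
               14 * log(f2$rss / 14) + 2 * K + 2 * K * (K + 1) / (14 - K - 1))
  expect_error(ols_fit(y, as.data.frame(cbind(X, X[, 1]))), "singular")
})

test_that("backward stepwise retains true effects and agrees with exhaustive search", {
  set.seed(53)
  contains <- 0; exact <- 0; agree <- 0
  reps <- 100
  for (r in 1:reps) {
    X <- as.data.frame(matrix(rnorm(14 * 6), 14, 6))
    names(X) <- c("A", "I", "PAR", "SI", "SR", "BS")
    y <- 2 * X$I + 2 * X$BS + rnorm(14, sd = 0.5)
    bs <- backward_stepwise_aicc(y, X)
    ex <- exhaustive_aicc(y, X)
    contains <- contains + all(c("I", "BS") %in% bs$fit$predictors)
    exact <- exact + setequal(bs$fit$predictors, c("I", "BS"))
    agree <- agree + identical(sort(bs$fit$predictors), sort(ex$best))
    # the accepted trace is strictly decreasing in AICc
    expect_true(all(diff(bs$trace$aicc) < 0))
  }
  expect_equal(contains / reps, 1)
  # min-AICc spuriously admits an extra predictor ~25% of the time at n = 14;
  # the exact-set recovery rate is ~0.75 by the exhaustive oracle
  expect_gt(exact / reps, 0.6)
  expect_gt(agree / reps, 0.9)
})

test_that("stepwise never crashes on pure noise and tends to the null model", {
  set.seed(54)
  k0 <- 0
  for (r in 1:40) {
    X <- as.data.frame(matrix(rnorm(14 * 6), 14, 6))
    bs <- backward_stepwise_aicc(rnorm(14), X)
    k0 <- k0 + (bs$fit$k == 0)
  }
  expect_gt(k0 / 40, 0.25)  # intercept-only is the modal outcome
  expect_error(backward_stepwise_aicc(rnorm(8), as.data.frame(matrix(rnorm(8 * 6), 8, 6))),
               "pre-screen")
})

test_that("variance partitioning sums to the full-model R2", {
  set.seed(55)
  n <- 40
  x1 <- rnorm(n); x2 <- residuals(lm(rnorm(n) ~ x1))
  y <- x1 + x2 + rnorm(n)
  vp <- variance_partition(y, x1, x2)
  expect_equal(vp$unique_1 + vp$unique_2 + vp$shared, vp$r2_full,
               tolerance = 1e-9)
  expect_equal(vp$unexplained, 1 - vp$r2_full, tolerance = 1e-12)
  # exactly orthogonal centered predictors: shared = 0
  x1c <- scale(x1, scale = FALSE)[, 1]
  x2c <- scale(x2, scale = FALSE)[, 1] -
    x1c * sum(x1c * scale(x2, scale = FALSE)) / sum(x1c^2)
  y2 <- x1c + x2c + rnorm(n)
  vp2 <- variance_partition(y2, x1c, x2c)
  expect_lt(abs(vp2$shared), 1e-9)
  # a duplicated predictor is pure redundancy
  vp3 <- variance_partition(y, x1, x1)
  expect_equal(vp3$unique_2, 0, tolerance = 1e-9)
  expect_equal(vp3$shared, vp3$r2_full, tolerance = 1e-9)
})

test_that("attribute aggregates reproduce the published survey summaries", {
  s <- tkl_island_survey()
  agg <- attribute_aggregates(s)
  iso <- agg[agg$attribute == "isolation_m", ]
  expect_equal(iso$mean, 718.71, tolerance = 1e-4)
  expect_equal(iso$sd, 257.76, tolerance = 1e-4)
  expect_equal(iso$min, 250); expect_equal(iso$max, 1121)
  sr <- agg[agg$attribute == "sex_ratio", ]
  expect_equal(sr$mean, 0.995, tolerance = 1e-3)
  expect_equal(sr$max, 1.875, tolerance = 1e-12)
  expect_equal(sr$min, 11 / 30, tolerance = 1e-12)
  mar <- mean(s$mar)
  expect_equal(mar, 7.87, tolerance = 1e-3)
  # a duplicated island has zero spread
  two <- s[c(1, 1), ]
  expect_true(all(attribute_aggregates(two)$sd == 0))
  # zero females: ratio excluded with a warning
  s2 <- s; s2$n_female[1] <- 0L
  expect_warning(a2 <- attribute_aggregates(s2), "zero females")
  expect_equal(a2$max[a2$attribute == "sex_ratio"], 1.875)
})
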