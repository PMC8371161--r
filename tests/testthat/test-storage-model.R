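test_that("noiseless series recover every published decay model exactly", {
  for (i in seq_len(nrow(decay_models()))) {
    dm <- decay_models()[i, ]
    s <- generate_storage_series(
      storage_series_spec(60, dm$slope, days = 30, intercept = dm$intercept))
    fit <- fit_linear(s$day, s$normalized_weight)
    expect_equal(fit$slope, dm$slope, tolerance = 1e-12)
    expect_equal(fit$intercept, dm$intercept, tolerance = 1e-12)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    expect_equal(fit$n, 31L)
  }
})

test_that("fit_linear matches the normal-equations oracle on random instances", {
  set.seed(40)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    x <- runif(n, -5, 5); y <- runif(n, -5, 5)
    if (var(x) == 0 || var(y) == 0) next
    got <- fit_linear(x, y); want <- ols_oracle(x, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-9)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-9)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-9)
  }
})

test_that("OLS passes through the centroid of the data", {
  set.seed(41)
  for (i in 1:20) {
    x <- runif(10); y <- runif(10)
    fit <- fit_linear(x, y)
    expect_equal(predict(fit, mean(x)), mean(y), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo slope recovery stays within the analytic OLS error", {
  true_slope <- -0.0031; sigma <- 0.002; days <- 30; reps <- 200
  slopes <- vapply(seq_len(reps), function(r) {
    s <- generate_storage_series(storage_series_spec(
      58, true_slope, days = days, noise_sigma = sigma, seed = 4000 + r))
    fit_linear(s$day, s$normalized_weight)$slope
  }, numeric(1))
  x <- 0:days
  se_single <- sigma / sqrt(sum((x - mean(x))^2))  # analytic per-series SE
  expect_lt(abs(mean(slopes) - true_slope), 3 * se_single / sqrt(reps))
  expect_lt(abs(mean(slopes) - true_slope), 2e-4)
  expect_equal(sd(slopes), se_single, tolerance = 0.25)
})

test_that("degenerate fits are flagged, not silently scored", {
  const <- fit_linear(0:10, rep(2, 11))
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_true(const$degenerate)
  expect_true(is.na(const$r_squared))
  expect_error(fit_linear(rep(1, 5), 1:5), "zero variance")
  expect_error(fit_linear(1, 1), "at least 2")
  expect_error(fit_linear(1:3, 1:4), "equal length")
})

test_that("prediction is the fitted line", {
  avg <- fit_linear(0:30, 1.0030 - 0.0028 * (0:30))
  expect_equal(predict(avg, 0), 1.0030, tolerance = 1e-12)
  expect_equal(predict(avg, 30), 0.9190, tolerance = 1e-12)
  flat <- fit_linear(c(0, 1, 2), rep(5, 3))
  expect_equal(predict(flat, c(-10, 100)), c(5, 5), tolerance = 1e-12)
})

test_that("freshness-density fit is an exact line when freshness comes from the ratio", {
  set.seed(42)
  rho_HE <- 1072.60e-6
  rho <- runif(25, 9.5e-4, 1.1e-3)
  fit <- fit_freshness_density(rho, freshness_percent(rho, rho_HE))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(fit$slope, 100 / rho_HE, tolerance = 1e-9)
  # noisy per-size simulation still gives a near-perfect linear relation
  s <- generate_storage_series(storage_series_spec(
    60, -0.0028, days = 30, noise_sigma = 0.002, seed = 43))
  dens <- s$normalized_weight * 1050e-6
  noisy <- fit_freshness_density(dens, freshness_percent(dens, 1072.60e-6))
  expect_gte(noisy$r_squared, 0.99)
})

test_that("agreement metrics reproduce hand-worked errors and definitions", {
  r <- c(100, 200, 300); m <- c(99, 202, 297)
  rep1 <- agreement_metrics(r, m)
  expect_equal(rep1$avg_relative_error, 1.0)
  expect_equal(rep1$max_relative_error, 1.0)
  expect_equal(rep1$avg_accuracy, 99.0)
  expect_equal(rep1$rmsec, sqrt(mean((m - r)^2)), tolerance = 1e-12)
  expect_equal(rep1$rpd, sd(r) / rep1$rmsec, tolerance = 1e-12)
  # identity: zero errors, infinite RPD
  id <- agreement_metrics(r, r)
  expect_equal(id$avg_relative_error, 0)
  expect_equal(id$rmsec, 0)
  expect_true(is.infinite(id$rpd))
  expect_equal(id$slope, 1, tolerance = 1e-12)
  # constructed SD/RMSE ratio recovered to 1e-9
  set.seed(44)
  ref <- runif(50, 50, 100)
  meas <- ref + rnorm(50, 0, 2)
  rep2 <- agreement_metrics(ref, meas)
  expect_equal(rep2$rpd, sd(ref) / sqrt(mean((meas - ref)^2)),
               tolerance = 1e-9)
  expect_error(agreement_metrics(c(0, 1), c(1, 1)), "positive")
})

test_that("agreement metrics are invariant under item permutation", {
  set.seed(45)
  ref <- runif(30, 50, 100); meas <- ref * runif(30, 0.97, 1.03)
  a <- agreement_metrics(ref, meas)
  p <- sample(30)
  b <- agreement_metrics(ref[p], meas[p])
  for (f in c("avg_relative_error", "max_relative_error", "avg_accuracy",
              "slope", "r_squared", "rmsec", "rpd")) {
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  }
})

test_that("fit_storage normalises raw weights by the day-0 value", {
  s <- generate_storage_series(
    storage_series_spec(64, -0.0029, days = 30, intercept = 1))
  fit <- fit_storage(s[, c("day", "weight")])
  expect_equal(fit$slope, -0.0029, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  path <- file.path(tempdir(), "series.csv")
  write.csv(s[, c("day", "weight")], path, row.names = FALSE)
  expect_equal(fit_storage(path)$slope, -0.0029, tolerance = 1e-10)
  expect_error(fit_storage(data.frame(day = 1:3, w = 1:3)), "column")
})
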