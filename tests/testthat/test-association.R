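test_that("with no covariates the partial correlation is the plain Pearson r", {
  withr::with_seed(21, {
    d <- tibble::tibble(x = rnorm(25), y = rnorm(25))
    out <- partial_correlation(d, "x", "y")
    expect_equal(out$r, cor(d$x, d$y))
    expect_equal(out$df, 23)
    ct <- cor.test(d$x, d$y)
    expect_equal(out$p, ct$p.value, tolerance = 1e-12)
  })
})

test_that("self-correlation is exactly 1 under any adjustment", {
  withr::with_seed(22, {
    d <- tibble::tibble(x = rnorm(20), g = rbinom(20, 1, 0.5), a = rnorm(20))
    d$y <- d$x
    out <- partial_correlation(d, "x", "y", covariates = c("g", "a"))
    expect_equal(out$r, 1)
    expect_equal(out$k, 2)
    expect_equal(out$df, 16)
  })
})

test_that("a fixed 12-row fixture matches the two-regression residual oracle", {
  d <- tibble::tibble(
    x = c(2.1, 3.4, 1.2, 5.6, 4.4, 3.3, 2.8, 6.1, 0.9, 4.0, 3.7, 5.2),
    y = c(1.0, 2.2, 0.7, 4.9, 3.1, 2.0, 3.3, 5.5, 1.4, 2.6, 4.1, 4.4),
    z = c(0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0)
  )
  out <- partial_correlation(d, "x", "y", covariates = "z")
  rx <- residuals(lm(x ~ z, data = d))
  ry <- residuals(lm(y ~ z, data = d))
  expect_equal(out$r, cor(rx, ry), tolerance = 1e-10)
  df <- 12 - 2 - 1
  t_or <- out$r * sqrt(df) / sqrt(1 - out$r^2)
  expect_equal(out$p, 2 * pt(-abs(t_or), df), tolerance = 1e-12)
  expect_equal(out$d_equiv, 2 * out$r / sqrt(1 - out$r^2))
})

test_that("covariates orthogonal to both variables leave r unchanged", {
  withr::with_seed(23, {
    x <- rnorm(30); y <- rnorm(30)
    z0 <- rnorm(30)
    z <- residuals(lm(z0 ~ x + y))  # exactly orthogonal to x, y, intercept
    d <- tibble::tibble(x = x, y = y, z = z)
    adj <- partial_correlation(d, "x", "y", covariates = "z")
    expect_equal(adj$r, cor(x, y), tolerance = 1e-10)
  })
})

test_that("degenerate inputs are reported as errors", {
  d <- tibble::tibble(x = rnorm(10), y = rnorm(10), z = 1:10)
  d$z2 <- 2 * d$z
  expect_error(partial_correlation(d, "x", "y", covariates = c("z", "z2")),
               "rank deficient")
  d$c <- 5
  expect_error(partial_correlation(d, "c", "y"), "zero-variance")
  d$y[1] <- NA
  expect_error(partial_correlation(d, "x", "y"), "missing")
  expect_error(partial_correlation(tibble::tibble(x = 1:3, y = 3:1, z = c(1, 2, 4)),
                                   "x", "y", covariates = "z"), "n > k \\+ 2")
})

test_that("partial-correlation p-values are uniform under the null", {
  withr::with_seed(24, {
    reps <- 2000
    n <- 30
    p <- numeric(reps)
    for (i in seq_len(reps)) {
      z <- rnorm(n)
      d <- tibble::tibble(z = z,
                          x = 0.5 * z + rnorm(n),
                          y = -0.3 * z + rnorm(n))
      p[i] <- partial_correlation(d, "x", "y", covariates = "z")$p
    }
    rate <- mean(p < 0.05)
    se <- sqrt(0.05 * 0.95 / reps)
    expect_gte(rate, 0.05 - 2 * se)
    expect_lte(rate, 0.05 + 2 * se)
  })
})

test_that("r-to-d conversion matches published values and is odd and increasing", {
  expect_equal(round(r_to_d(-0.10), 2), -0.20)
  expect_equal(round(r_to_d(0.06), 2), 0.12)
  expect_equal(r_to_d(0), 0)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(r_to_d(-r), -r_to_d(r))
  expect_true(all(diff(r_to_d(r)) > 0))
  expect_warning(r_to_d(1), "infinite")
})

test_that("one-sample t matches hand arithmetic and summary-statistic input", {
  out <- one_sample_t(c(1, 2, 3, 4), mu0 = 0)
  expect_equal(out$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(out$df, 3)
  tt <- t.test(c(1, 2, 3, 4), mu = 0)
  expect_equal(out$p, tt$p.value, tolerance = 1e-12)

  null <- one_sample_t(c(2, 4, 6), mu0 = 4)
  expect_equal(null$t, 0)
  expect_equal(null$d, 0)

  summ <- one_sample_t_summary(0.62, 0.23, 208, 0.5)
  expect_equal(round(summ$d, 2), 0.52)
  expect_equal(summ$df, 207)
  expect_error(one_sample_t(c(3, 3, 3), 0), "variance")
})

test_that("pooled d matches its closed form", {
  expect_equal(pooled_d(1, 1, 10, 1, 1, 10), 0)
  expect_equal(round(pooled_d(0.47, 0.14, 92, 0.41, 0.14, 105), 2), 0.43)
  expect_equal(pooled_d(2, 0.5, 30, 1, 0.5, 40), 1 / 0.5)
  expect_error(pooled_d(1, 0, 5, 1, 0, 5), "pooled variance")
})

test_that("t-test power functions are calibrated at zero effect and monotone", {
  expect_equal(power_two_sample_t(0, 20, 25), 0.05, tolerance = 1e-10)
  expect_equal(power_one_sample_t(0, 30), 0.05, tolerance = 1e-10)
  expect_gt(power_two_sample_t(3, 20, 20), 0.999)
  d <- seq(0.1, 1.2, by = 0.1)
  expect_true(all(diff(vapply(d, power_two_sample_t, 1, n1 = 30, n2 = 30)) > 0))
  ns <- c(10, 20, 40, 80, 160)
  expect_true(all(diff(vapply(ns, function(n) power_one_sample_t(0.4, n), 1)) > 0))
})

test_that("one-sample power matches a brute-force simulation", {
  analytic <- power_one_sample_t(0.3, 20)
  withr::with_seed(25, {
    reps <- 1e5
    x <- matrix(rnorm(20 * reps, mean = 0.3), nrow = 20)
    m <- colMeans(x)
    v <- (colMeans(x^2) - m^2) * 20 / 19
    tstat <- m / sqrt(v / 20)
    sim <- mean(abs(tstat) > qt(0.975, 19))
  })
  expect_equal(analytic, sim, tolerance = 0.01)
})

test_that("correlation power matches a Fisher-z simulation and its size at r = 0", {
  expect_equal(power_correlation(0, 50), 0.05, tolerance = 1e-12)
  analytic <- power_correlation(0.5, 100, k = 0)
  withr::with_seed(26, {
    reps <- 1e4
    n <- 100
    x <- matrix(rnorm(n * reps), nrow = n)
    y <- 0.5 * x + sqrt(1 - 0.25) * matrix(rnorm(n * reps), nrow = n)
    mx <- colMeans(x); my <- colMeans(y)
    sx <- sqrt(colMeans(x^2) - mx^2); sy <- sqrt(colMeans(y^2) - my^2)
    r <- (colMeans(x * y) - mx * my) / (sx * sy)
    z <- atanh(r) * sqrt(n - 3)
    sim <- mean(z > qnorm(0.95))
  })
  expect_equal(analytic, sim, tolerance = 0.02)
  rr <- seq(0.05, 0.6, by = 0.05)
  expect_true(all(diff(vapply(rr, power_correlation, 1, n = 80)) > 0))
})
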