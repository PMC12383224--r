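#' Covariate-adjusted (partial) Pearson correlation with effect size and power
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares and returns the Pearson correlation of the residuals. The
#' p-value uses \eqn{t = r \sqrt{df} / \sqrt{1 - r^2}} with
#' `df = n - 2 - k` (k = number of covariates). The Cohen's d equivalent is
#' [r_to_d()] and the achieved power comes from [power_correlation()] at the
#' observed `|r|`.
#'
#' @param data A data frame containing all columns.
#' @param x,y Names (strings) of the two variables of interest.
#' @param covariates Character vector of covariate column names (may be
#'   empty, giving the plain Pearson correlation).
#' @param alpha Significance level used for the power column (default 0.05).
#' @param tails Tail convention passed to [power_correlation()] (default
#'   `"one"`).
#' @return A one-row tibble: `x`, `y`, `r`, `n`, `k`, `df`, `p`, `d_equiv`,
#'   `power`.
#' @export
#' @examples
#' d <- tibble::tibble(a = rnorm(30), b = rnorm(30), g = rbinom(30, 1, 0.5))
#' partial_correlation(d, "a", "b", covariates = "g")
partial_correlation <- function(data, x, y, covariates = character(),
                                alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  require_columns(data, c(x, y, covariates), "data")
  cols <- c(x, y, covariates)
  sub <- data[, cols, drop = FALSE]
  if (anyNA(sub)) abort("missing values present; screen the data upstream.")
  n <- nrow(sub)
  k <- length(covariates)
  if (n <= k + 2) abort("need n > k + 2 observations for a partial correlation.")

  xv <- as.numeric(sub[[x]])
  yv <- as.numeric(sub[[y]])
  if (k > 0) {
    Z <- cbind(`(Intercept)` = 1,
               as.matrix(as.data.frame(lapply(sub[covariates], as.numeric))))
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) abort("covariate matrix is rank deficient.")
    xv <- qr.resid(qz, xv)
    yv <- qr.resid(qz, yv)
  } else {
    xv <- xv - mean(xv)
    yv <- yv - mean(yv)
  }
  if (sd(xv) == 0 || sd(yv) == 0) abort("zero-variance residuals; correlation undefined.")

  r <- cor(xv, yv)
  df <- n - 2 - k
  tval <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tval), df)
  tibble::tibble(
    x = x, y = y, r = r, n = n, k = k, df = df, p = p,
    d_equiv = r_to_d(r),
    power = power_correlation(abs(r), n, k = k, alpha = alpha, tails = tails)
  )
}

#' Convert a correlation to a Cohen's d equivalent
#'
#' `d = 2 r / sqrt(1 - r^2)`; odd and strictly increasing on (-1, 1). Returns
#' signed infinity (with a warning) at `|r| = 1`.
#'
#' @param r Correlation(s) with `|r| <= 1`.
#' @return Cohen's d equivalent(s), same sign as `r`.
#' @export
#' @examples
#' r_to_d(-0.10)
r_to_d <- function(r) {
  assert_numeric_in(r, -1, 1, "r")
  if (any(abs(r) == 1)) {
    rlang::warn("|r| = 1 converts to an infinite Cohen's d.")
  }
  2 * r / sqrt(1 - r^2)
}

#' One-sample t-test with Cohen's d
#'
#' @param values Numeric vector (n >= 2, positive variance).
#' @param mu0 Null value.
#' @return A one-row tibble: `estimate` (mean), `t`, `df`, `p` (two-sided),
#'   `d` (`(M - mu0) / SD`).
#' @export
#' @examples
#' one_sample_t(c(1, 2, 3, 4), mu0 = 0)
one_sample_t <- function(values, mu0) {
  if (length(values) < 2) abort("one_sample_t needs at least 2 values.")
  if (anyNA(values)) abort("values contain missing data.")
  one_sample_t_summary(mean(values), sd(values), length(values), mu0)
}

#' @rdname one_sample_t
#' @param m,s,n Sample mean, standard deviation and size (summary-statistic
#'   interface).
#' @export
one_sample_t_summary <- function(m, s, n, mu0) {
  if (s <= 0) abort("zero variance: the t statistic is undefined.")
  tval <- (m - mu0) / (s / sqrt(n))
  df <- n - 1
  tibble::tibble(
    estimate = m, t = tval, df = df,
    p = 2 * pt(-abs(tval), df),
    d = (m - mu0) / s
  )
}

#' Pooled-SD Cohen's d for two independent groups
#'
#' `d = (m1 - m2) / s_p` with
#' `s_p^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`.
#'
#' @param m1,sd1,n1 Mean, SD, size of group 1.
#' @param m2,sd2,n2 Mean, SD, size of group 2.
#' @return Cohen's d.
#' @export
#' @examples
#' pooled_d(0.47, 0.14, 92, 0.41, 0.14, 105)
pooled_d <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2.")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("zero pooled variance: d is undefined.")
  (m1 - m2) / sqrt(sp2)
}

#' Power of the two-sample t-test (noncentral t)
#'
#' `ncp = d * sqrt(n1 n2 / (n1 + n2))`, `df = n1 + n2 - 2`. The default tail
#' convention is two-tailed.
#'
#' @param d Cohen's d.
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Significance level.
#' @param tails `"two"` (default) or `"one"`.
#' @return Power (1 - beta).
#' @export
#' @examples
#' power_two_sample_t(0.44, 92, 105)
power_two_sample_t <- function(d, n1, n2, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  stopifnot(is.finite(d), n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  noncentral_t_power(ncp, df, alpha, tails)
}

#' Power of the one-sample t-test (noncentral t)
#'
#' `ncp = d * sqrt(n)`, `df = n - 1`.
#'
#' @inheritParams power_two_sample_t
#' @param n Sample size (>= 2).
#' @return Power (1 - beta).
#' @export
#' @examples
#' power_one_sample_t(0.52, 208)
power_one_sample_t <- function(d, n, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  stopifnot(is.finite(d), n >= 2, alpha > 0, alpha < 1)
  noncentral_t_power(d * sqrt(n), n - 1, alpha, tails)
}

#' @noRd
noncentral_t_power <- function(ncp, df, alpha, tails) {
  if (tails == "two") {
    tcrit <- qt(1 - alpha / 2, df)
    pt(tcrit, df, ncp = ncp, lower.tail = FALSE) + pt(-tcrit, df, ncp = ncp)
  } else {
    tcrit <- qt(1 - alpha, df)
    pt(tcrit, df, ncp = abs(ncp), lower.tail = FALSE)
  }
}

#' Power of a (partial) correlation test via the Fisher-z approximation
#'
#' `z_r = atanh(|r|)`, `SE = 1 / sqrt(n - k - 3)`; one-tailed power is
#' \eqn{\Phi(z_r / SE - z_{1-\alpha})} (the default convention), two-tailed
#' uses \eqn{z_{1-\alpha/2}} on both sides.
#'
#' @param r Population (or observed) correlation, `|r| < 1`.
#' @param n Sample size, `n > k + 3`.
#' @param k Number of covariates partialled out (default 0).
#' @param alpha Significance level.
#' @param tails `"one"` (default) or `"two"`.
#' @return Power (1 - beta).
#' @export
#' @examples
#' power_correlation(0.10, 197, k = 1)
power_correlation <- function(r, n, k = 0, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(abs(r) < 1, n > k + 3, alpha > 0, alpha < 1)
  zr <- atanh(abs(r))
  se <- 1 / sqrt(n - k - 3)
  if (tails == "one") {
    pnorm(zr / se - qnorm(1 - alpha))
  } else {
    pnorm(zr / se - qnorm(1 - alpha / 2)) + pnorm(-zr / se - qnorm(1 - alpha / 2))
  }
}
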