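# Fitting the allometric law and the method-agreement statistics used to
# compare growth-rate proxies against the in situ reference: RMSE, Lin's
# concordance correlation coefficient with its asymptotic confidence
# interval, and regression through the origin.

#' Fit the leaf allometry w = alpha * l^beta
#'
#' Nonlinear least squares on the arithmetic scale, initialized from the
#' closed-form log-log ordinary least squares solution.  Leaf dry-weight
#' scatter about the power law is multiplicative (variance grows with the
#' fitted mean), so the arithmetic-scale criterion is relative least
#' squares: residuals are weighted by the inverse squared fitted value,
#' iteratively reweighted from the log-log start.  The arithmetic
#' R-squared (`1 - SSE/SST` on weights, unweighted) is the primary
#' goodness-of-fit figure; the log-scale R-squared of the initializing fit
#' is also kept.
#'
#' @param lengths Leaf lengths (mm), all > 0, not all equal.
#' @param weights Leaf dry weights (g), all > 0.
#' @return An object of class `allometry_fit`: `params`
#'   ([allometric_params()]), `r_squared` (arithmetic), `r_squared_log`,
#'   `n`, and a residual summary.
#' @examples
#' l <- seq(50, 600, length.out = 50)
#' fit_allometry(l, 2e-5 * l^1.3)
#' @export
fit_allometry <- function(lengths, weights) {
  if (length(lengths) != length(weights)) {
    zg_stop_usage("`lengths` and `weights` must have equal length")
  }
  ok <- is.finite(lengths) & is.finite(weights)
  lengths <- lengths[ok]; weights <- weights[ok]
  n <- length(lengths)
  if (n < 3L) zg_stop_domain("at least 3 length/weight pairs are required")
  if (any(lengths <= 0) || any(weights <= 0)) {
    zg_stop_domain("lengths and weights must be strictly positive")
  }
  if (diff(range(lengths)) < 1e-12 * max(lengths)) {
    zg_stop(paste("allometric model is unidentifiable:",
                  "all lengths are (numerically) equal"),
            "zg_unidentifiable_error")
  }

  # Closed-form log-log OLS: log w = log alpha + beta log l.
  x <- log(lengths); y <- log(weights)
  beta0 <- stats::cov(x, y) / stats::var(x)
  alpha0 <- exp(mean(y) - beta0 * mean(x))
  r2_log <- stats::cor(x, y)^2

  est <- c(alpha = alpha0, beta = beta0)
  for (it in 1:3) {
    wts <- 1 / pmax(est[["alpha"]] * lengths^est[["beta"]],
                    .Machine$double.xmin)^2
    fit <- tryCatch(
      stats::nls(weights ~ alpha * lengths^beta, weights = wts,
                 start = list(alpha = est[["alpha"]], beta = est[["beta"]]),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE,
                                              scaleOffset = 1)),
      error = function(e) NULL)
    if (is.null(fit)) break
    cand <- stats::coef(fit)
    if (cand[["alpha"]] <= 0 || cand[["beta"]] <= 0) break
    est <- cand
  }

  pred <- est[["alpha"]] * lengths^est[["beta"]]
  resid <- weights - pred
  sse <- sum(resid^2)
  sst <- sum((weights - mean(weights))^2)

  structure(
    list(params = allometric_params(est[["alpha"]], est[["beta"]]),
         r_squared = 1 - sse / sst,
         r_squared_log = r2_log,
         n = n,
         start = allometric_params(alpha0, max(beta0, .Machine$double.eps)),
         residuals = summary(resid),
         rmse = sqrt(mean(resid^2))),
    class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf(
    "<allometry_fit> n = %d: alpha = %.4g, beta = %.4g; R2 = %.4f (arithmetic), %.4f (log-log)\n",
    x$n, x$params$alpha, x$params$beta, x$r_squared, x$r_squared_log))
  invisible(x)
}

#' Root mean squared error
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    zg_stop_usage("`observed` and `predicted` must have equal length")
  }
  if (!length(observed)) zg_stop_usage("vectors must be non-empty")
  sqrt(mean((observed - predicted)^2))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of two measurements of the same quantity, combining precision
#' (Pearson correlation) and accuracy (departure of the best-fit line from
#' the 45-degree identity):
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (1/n) moments.  The confidence interval uses Lin's asymptotic
#' variance on the inverse-hyperbolic-tangent (Fisher z) scale.
#'
#' @param observed,predicted Equal-length numeric vectors, n >= 3, not both
#'   constant.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list: `rho_c`, `ci_lower`, `ci_upper`, `n`, plus the Pearson
#'   `r` and the accuracy factor `c_b = rho_c / r`.
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
lin_ccc <- function(observed, predicted, conf_level = 0.95) {
  x <- observed; y <- predicted
  if (length(x) != length(y)) {
    zg_stop_usage("`observed` and `predicted` must have equal length")
  }
  n <- length(x)
  if (n < 3L) zg_stop_domain("at least 3 pairs are required")
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  if (sx2 == 0 && sy2 == 0) {
    zg_stop("concordance is undefined: both vectors are constant",
            "zg_undefined_coefficient_error")
  }
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  u <- mean(x) - mean(y)
  rho_c <- 2 * sxy / (sx2 + sy2 + u^2)

  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else 0
  c_b <- if (r != 0) rho_c / r else NA_real_

  # Lin (1989, corrected 2000) asymptotic variance of the z-transformed
  # estimate; v = scaled mean shift.
  if (abs(rho_c) < 1 && r != 0 && sx2 > 0 && sy2 > 0 && n > 2) {
    v2 <- u^2 / sqrt(sx2 * sy2)
    s2z <- (1 / (n - 2)) *
      ((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
         2 * rho_c^3 * (1 - rho_c) * v2 / (r * (1 - rho_c^2)^2) -
         rho_c^4 * v2^2 / (2 * r^2 * (1 - rho_c^2)^2))
    s2z <- max(s2z, 0)
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    z <- atanh(rho_c)
    ci <- tanh(z + c(-1, 1) * zq * sqrt(s2z))
  } else {
    ci <- c(rho_c, rho_c)
  }

  list(rho_c = rho_c, ci_lower = min(ci[1], rho_c), ci_upper = max(ci[2], rho_c),
       n = n, r = r, c_b = c_b, conf_level = conf_level)
}

#' Regression through the origin
#'
#' Least-squares slope constrained through (0, 0), `slope = sum(xy) /
#' sum(x^2)`, with the coefficient of determination computed against the
#' through-origin model but a centred total sum of squares
#' (`1 - SSE / sum((y - mean(y))^2)`), so that a proportional relationship
#' scores near 1 and a poor proportional fit can score near (or below) 0.
#' A companion ordinary fit with intercept is included for the case where
#' the through-origin model is inadequate.
#'
#' @param x,y Equal-length numeric vectors, n >= 2; `sum(x^2) > 0`.
#' @return A list: `slope`, `r_squared`, `n`, and `with_intercept` (slope,
#'   intercept, r_squared of the ordinary fit).
#' @examples
#' regression_through_origin(c(1, 2), c(2, 2))  # slope 1.2
#' @export
regression_through_origin <- function(x, y) {
  if (length(x) != length(y)) zg_stop_usage("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2L) zg_stop_domain("at least 2 pairs are required")
  sxx <- sum(x^2)
  if (sxx == 0) {
    zg_stop("through-origin slope is undefined: all x are zero",
            "zg_undefined_slope_error")
  }
  slope <- sum(x * y) / sxx
  sse <- sum((y - slope * x)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else as.numeric(sse == 0)

  wi <- if (n >= 3 && stats::var(x) > 0) {
    fit <- stats::lm(y ~ x)
    sse_i <- sum(stats::residuals(fit)^2)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = if (sst > 0) 1 - sse_i / sst else as.numeric(sse_i == 0))
  } else list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_)

  list(slope = slope, r_squared = r2, n = n, with_intercept = wi)
}
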