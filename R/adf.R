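# Dickey-Fuller critical values for the constant, no-trend (drift) case,
# tabulated by sample size; p-values interpolate this surface, the same
# device classical time-series packages use.
adf_table_drift <- local({
  probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  ns <- c(25, 50, 100, 250, 500, 1e9)
  vals <- rbind(
    c(-3.75, -3.33, -3.00, -2.63, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)
  )
  list(probs = probs, ns = ns, vals = vals)
})

#' Augmented Dickey-Fuller unit-root test
#'
#' Tests the null of a unit root against stationarity using the regression
#' `diff(y)_t = alpha + rho * y_{t-1} + sum_i gamma_i diff(y)_{t-i} + e_t`
#' (constant included, no trend -- the "drift" case appropriate for
#' regression residuals and log-volume series). The test statistic is the
#' t-ratio on `rho`; its p-value is obtained by interpolating the
#' Dickey-Fuller distribution's tabulated quantiles in both sample size and
#' probability, clamped to \[0.01, 0.99\].
#'
#' @param y numeric series (NA-free, length >= 12).
#' @param lags number of lagged differences; default
#'   `trunc((length(y) - 1)^(1/3))`.
#' @return list of class `adf_test` with `statistic`, `p.value`, `lags`,
#'   `n`, and `verdict` (`"stationary"` if p <= 0.05, `"non-stationary"`
#'   otherwise, `"inconclusive"` for degenerate input).
#' @export
#' @examples
#' adf_test(rnorm(200))$verdict            # "stationary" almost always
#' adf_test(cumsum(rnorm(200)))$p.value    # large: unit root not rejected
adf_test <- function(y, lags = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stop_input("adf_test: series contains NA")
  n <- length(y)
  if (n < 12) {
    return(structure(list(statistic = NA_real_, p.value = NA_real_,
                          lags = NA_integer_, n = n,
                          verdict = "inconclusive"),
                     class = "adf_test"))
  }
  if (sd(y) < .Machine$double.eps^0.5) {
    return(structure(list(statistic = NA_real_, p.value = NA_real_,
                          lags = 0L, n = n, verdict = "inconclusive"),
                     class = "adf_test"))
  }
  if (is.null(lags)) lags <- trunc((n - 1)^(1 / 3))
  lags <- as.integer(lags)
  dy <- diff(y)
  m <- length(dy)
  idx <- (lags + 1):m
  X <- cbind(lag_y = y[idx], 1)
  if (lags > 0) {
    lagged <- sapply(seq_len(lags), function(i) dy[idx - i])
    X <- cbind(X, lagged)
  }
  fit <- stats::lm.fit(x = X, y = dy[idx])
  res <- fit$residuals
  df <- length(idx) - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se_rho <- sqrt(s2 * XtXinv[1, 1])
  stat <- fit$coefficients[1] / se_rho
  p <- interp_adf_p(stat, n)
  verdict <- if (is.na(p)) "inconclusive"
             else if (p <= 0.05) "stationary" else "non-stationary"
  structure(list(statistic = unname(stat), p.value = p, lags = lags, n = n,
                 verdict = verdict),
            class = "adf_test")
}

interp_adf_p <- function(stat, n) {
  tab <- adf_table_drift
  # interpolate critical values at this n, then invert stat -> p
  crit <- vapply(seq_along(tab$probs), function(j) {
    approx(tab$ns, tab$vals[, j], xout = n, rule = 2)$y
  }, numeric(1))
  p <- approx(crit, tab$probs, xout = stat, rule = 2)$y
  min(max(p, 0.01), 0.99)
}

#' @export
print.adf_test <- function(x, ...) {
  cat(sprintf("<adf_test> stat = %.3f, lags = %s, n = %d, p %s %.2f -> %s\n",
              x$statistic, x$lags, x$n,
              if (!is.na(x$p.value) && (x$p.value <= 0.01 || x$p.value >= 0.99))
                "at bound" else "=",
              x$p.value, x$verdict))
  invisible(x)
}
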