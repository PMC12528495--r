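#' Fit a pre-period SARIMAX model
#'
#' Fits a seasonal ARIMA model with exogenous regressors to the pre-policy
#' span of a daily series, either at fixed orders or by a stepwise
#' information-criterion search over `(p, q)(P, Q)` in the spirit of
#' automatic ARIMA order selection: start from a small set of standard
#' candidates, then move to the best AIC neighbour (one order up or down at
#' a time) until no improvement, with orders capped at `p, q <= 5` and
#' `P, Q <= 2` to bound runtime. Exogenous regressors enter as a linear
#' regression with SARIMA errors, which is how policy-phase dummies are
#' absorbed during fitting.
#'
#' Non-convergence at fixed orders walks a retry ladder: maximum-likelihood
#' with CSS starting values, then pure CSS, then first differencing, then a
#' fallback AR(1); every fallback is recorded in the returned object.
#'
#' @param y numeric series (pre-period, already imputed/complete).
#' @param order `"auto"` or fixed `c(p, d, q)`.
#' @param seasonal fixed `c(P, D, Q)` seasonal orders, or `"auto"` (searched
#'   when `order = "auto"`).
#' @param period seasonal period S; 7 for daily data with a weekly rhythm,
#'   1 disables seasonality.
#' @param xreg optional numeric matrix of exogenous regressors (rows match
#'   `y`); constant columns are dropped with a note.
#' @param max_order caps `c(p_max, q_max, P_max, Q_max)` for the search.
#' @return An object of class `sarimax_fit`: the `stats::arima` fit plus
#'   orders, period, regressor names, the data, AIC, a Ljung-Box residual
#'   p-value, and any fallbacks taken.
#' @export
fit_pre_period <- function(y, order = "auto", seasonal = c(0, 0, 0),
                           period = 7, xreg = NULL,
                           max_order = c(5, 5, 2, 2)) {
  y <- as.numeric(y)
  if (anyNA(y)) stop_input("series contains NA; impute before fitting")
  dropped_cols <- character(0)
  if (!is.null(xreg)) {
    xreg <- as.matrix(xreg)
    if (is.null(colnames(xreg))) {
      colnames(xreg) <- paste0("x", seq_len(ncol(xreg)))
    }
    keep <- apply(xreg, 2, function(col) var(col) > 0)
    dropped_cols <- colnames(xreg)[!keep]
    xreg <- xreg[, keep, drop = FALSE]
    if (ncol(xreg) > 0) {
      # drop regressors that are collinear with the intercept and the rest
      # (e.g. phase dummies tiling the whole fit span need a reference phase)
      q <- qr(cbind(1, xreg))
      if (q$rank < ncol(xreg) + 1) {
        keep_idx <- sort(q$pivot[seq_len(q$rank)])
        keep_idx <- setdiff(keep_idx, 1L) - 1L
        dropped_cols <- c(dropped_cols,
                          setdiff(colnames(xreg), colnames(xreg)[keep_idx]))
        xreg <- xreg[, keep_idx, drop = FALSE]
      }
    }
    if (ncol(xreg) == 0) xreg <- NULL
  }
  if (identical(order, "auto")) {
    res <- search_orders(y, xreg, period, max_order,
                         seasonal = if (identical(seasonal, "auto")) NULL
                                    else seasonal)
  } else {
    res <- fit_with_ladder(y, order, seasonal, period, xreg)
  }
  fit <- res$fit
  orders <- res$order
  sorders <- res$seasonal
  n_coef <- sum(orders[c(1, 3)], sorders[c(1, 3)])
  lb <- tryCatch(
    Box.test(residuals(fit), lag = max(n_coef + 1, 10), type = "Ljung-Box",
             fitdf = n_coef)$p.value,
    error = function(e) NA_real_)
  structure(
    list(fit = fit,
         order = orders,
         seasonal = sorders,
         period = period,
         xreg_names = if (is.null(xreg)) character(0) else colnames(xreg),
         xreg = xreg,
         y = y,
         sigma2 = fit$sigma2,
         aic = fit$aic,
         ljung_box_p = lb,
         dropped_regressors = dropped_cols,
         fallbacks = res$fallbacks),
    class = "sarimax_fit"
  )
}

#' @export
print.sarimax_fit <- function(x, ...) {
  cat(sprintf("<sarimax_fit> (%d,%d,%d)(%d,%d,%d)[%d], n = %d, AIC = %.2f\n",
              x$order[1], x$order[2], x$order[3],
              x$seasonal[1], x$seasonal[2], x$seasonal[3],
              x$period, length(x$y), x$aic))
  if (length(x$xreg_names)) {
    cat("  regressors:", paste(x$xreg_names, collapse = ", "), "\n")
  }
  if (length(x$fallbacks)) {
    cat("  fallbacks:", paste(x$fallbacks, collapse = " -> "), "\n")
  }
  invisible(x)
}

try_arima <- function(y, order, seasonal, period, xreg, method = "CSS-ML") {
  tryCatch(
    suppressWarnings(arima(
      y, order = order,
      seasonal = list(order = seasonal, period = period),
      xreg = xreg, method = method,
      optim.control = list(maxit = 500))),
    error = function(e) NULL)
}

fit_with_ladder <- function(y, order, seasonal, period, xreg) {
  fallbacks <- character(0)
  fit <- try_arima(y, order, seasonal, period, xreg)
  if (is.null(fit)) {
    fallbacks <- c(fallbacks, "method=CSS")
    fit <- try_arima(y, order, seasonal, period, xreg, method = "CSS")
  }
  if (is.null(fit) && order[2] == 0) {
    fallbacks <- c(fallbacks, "d+1")
    order2 <- order + c(0, 1, 0)
    fit <- try_arima(y, order2, seasonal, period, xreg)
    if (!is.null(fit)) {
      return(list(fit = fit, order = order2, seasonal = seasonal,
                  fallbacks = fallbacks))
    }
  }
  if (is.null(fit)) {
    fallbacks <- c(fallbacks, "fixed (1,0,0)(0,0,0)")
    order <- c(1, 0, 0)
    seasonal <- c(0, 0, 0)
    fit <- try_arima(y, order, seasonal, period, xreg)
  }
  if (is.null(fit)) {
    stop_input("SARIMAX fit failed after retry ladder (orders ",
               paste(order, collapse = ","), "; n = ", length(y), ")")
  }
  list(fit = fit, order = order, seasonal = seasonal, fallbacks = fallbacks)
}

# stepwise AIC search over (p,q)(P,Q); d, D fixed at 0 unless a unit root is
# indicated by the ADF test, in which case d = 1
search_orders <- function(y, xreg, period, max_order, seasonal = NULL) {
  d <- 0
  adf <- tryCatch(adf_test(y), error = function(e) NULL)
  if (!is.null(adf) && !is.na(adf$p.value) && adf$p.value > 0.05) d <- 1
  D <- if (is.null(seasonal)) 0 else seasonal[2]
  search_seasonal <- is.null(seasonal) && period > 1
  if (!is.null(seasonal)) {
    PQ <- seasonal[c(1, 3)]
  } else if (!search_seasonal) {
    PQ <- c(0, 0)
  }
  cand <- list(c(2, 2), c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  best <- NULL
  best_aic <- Inf
  seen <- character(0)
  eval_model <- function(p, q, P, Q) {
    key <- paste(p, q, P, Q, sep = "_")
    if (key %in% seen) return(NULL)
    seen <<- c(seen, key)
    fit <- try_arima(y, c(p, d, q), c(P, D, Q), period, xreg)
    if (is.null(fit)) return(NULL)
    list(fit = fit, p = p, q = q, P = P, Q = Q, aic = fit$aic)
  }
  starts <- lapply(cand, function(pq) {
    if (search_seasonal) {
      eval_model(pq[1], pq[2], min(1, max_order[3]), min(1, max_order[4]))
    } else {
      eval_model(pq[1], pq[2], PQ[1], PQ[2])
    }
  })
  for (m in starts) {
    if (!is.null(m) && m$aic < best_aic) { best <- m; best_aic <- m$aic }
  }
  if (is.null(best)) {
    res <- fit_with_ladder(y, c(1, d, 0), c(0, D, 0), period, xreg)
    res$fallbacks <- c("search failed", res$fallbacks)
    return(res)
  }
  repeat {
    improved <- FALSE
    steps <- list(c(1, 0, 0, 0), c(-1, 0, 0, 0), c(0, 1, 0, 0),
                  c(0, -1, 0, 0))
    if (search_seasonal) {
      steps <- c(steps, list(c(0, 0, 1, 0), c(0, 0, -1, 0),
                             c(0, 0, 0, 1), c(0, 0, 0, -1)))
    }
    for (s in steps) {
      p <- best$p + s[1]; q <- best$q + s[2]
      P <- best$P + s[3]; Q <- best$Q + s[4]
      if (p < 0 || q < 0 || P < 0 || Q < 0 ||
          p > max_order[1] || q > max_order[2] ||
          P > max_order[3] || Q > max_order[4]) next
      m <- eval_model(p, q, P, Q)
      if (!is.null(m) && m$aic < best_aic - 1e-8) {
        best <- m; best_aic <- m$aic; improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(fit = best$fit, order = c(best$p, d, best$q),
       seasonal = c(best$P, D, best$Q), fallbacks = character(0))
}

# polynomial product (convolution) of coefficient vectors in L
poly_mult <- function(a, b) {
  if (length(a) == 0) return(b)
  if (length(b) == 0) return(a)
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

seasonal_poly <- function(coefs, period, sign) {
  if (length(coefs) == 0) return(1)
  out <- numeric(length(coefs) * period + 1)
  out[1] <- 1
  out[seq_along(coefs) * period + 1] <- sign * coefs
  out
}

diff_poly <- function(d, period = 1) {
  out <- 1
  base <- numeric(period + 1)
  base[1] <- 1
  base[period + 1] <- -1
  for (i in seq_len(d)) out <- poly_mult(out, base)
  out
}

# expand a fitted SARIMA into full AR (including differencing) and MA
# lag-polynomial coefficients on the regression-adjusted scale
expand_sarima <- function(sfit) {
  cf <- coef(sfit$fit)
  p <- sfit$order[1]; d <- sfit$order[2]; q <- sfit$order[3]
  P <- sfit$seasonal[1]; D <- sfit$seasonal[2]; Q <- sfit$seasonal[3]
  S <- sfit$period
  ar <- if (p > 0) unname(cf[paste0("ar", seq_len(p))]) else numeric(0)
  ma <- if (q > 0) unname(cf[paste0("ma", seq_len(q))]) else numeric(0)
  sar <- if (P > 0) unname(cf[paste0("sar", seq_len(P))]) else numeric(0)
  sma <- if (Q > 0) unname(cf[paste0("sma", seq_len(Q))]) else numeric(0)
  ar_poly <- poly_mult(
    poly_mult(c(1, -ar), seasonal_poly(sar, S, -1)),
    poly_mult(diff_poly(d), diff_poly(D, S)))
  ma_poly <- poly_mult(c(1, ma), seasonal_poly(sma, S, 1))
  mu <- if ("intercept" %in% names(cf)) unname(cf["intercept"]) else 0
  beta <- if (length(sfit$xreg_names)) unname(cf[sfit$xreg_names]) else numeric(0)
  list(ar = ar_poly, ma = ma_poly, mu = mu, beta = beta)
}

# regression-adjusted history and innovations of a sarimax_fit
adjusted_history <- function(sfit, poly) {
  w <- sfit$y - poly$mu
  if (length(poly$beta) > 0) {
    w <- w - as.numeric(sfit$xreg %*% poly$beta)
  }
  list(w = w, e = as.numeric(residuals(sfit$fit)))
}

#' Simulate counterfactual forecast paths from a fitted SARIMAX model
#'
#' Draws `B` simulated continuation paths of length `horizon` from the
#' fitted model, conditional on the observed pre-period: the full AR
#' polynomial (autoregressive, seasonal, and differencing factors expanded)
#' is iterated forward from the tail of the regression-adjusted history,
#' feeding the fitted innovations into the MA terms and drawing new
#' innovations from the fitted Gaussian N(0, sigma^2). Parameters are held
#' at their estimates (no parameter-uncertainty propagation). For each path
#' the forecast-horizon mean `M_k` is recorded; their Monte-Carlo mean
#' `m_hat` and standard deviation `s_hat` summarise the counterfactual
#' distribution that downstream Z statistics compare against.
#'
#' @param sfit a `sarimax_fit` from [fit_pre_period()].
#' @param horizon k, number of days to forecast (> 0).
#' @param B number of simulated paths (>= 2; 1000 by default).
#' @param seed integer seed making the draw reproducible.
#' @param xreg_future matrix of exogenous regressor values over the horizon
#'   (columns matching the fitted regressors). For a counterfactual, the
#'   evaluated policy's dummy is held at 0 while earlier phases keep their
#'   actual values. Required iff the fit used regressors.
#' @return An object of class `counterfactual_summary` with elements `M`
#'   (the B path means), `m_hat`, `s_hat`, `k`, `B`, `paths` (only if
#'   `keep_paths`), awaiting completion by [single_series_z()].
#' @param keep_paths retain the simulated path matrix (B x k).
#' @export
simulate_counterfactual <- function(sfit, horizon, B = 1000, seed = 1L,
                                    xreg_future = NULL, keep_paths = FALSE) {
  if (horizon <= 0) stop_input("horizon k must be > 0")
  if (B < 2) stop_input("B must be >= 2")
  poly <- expand_sarima(sfit)
  if (length(poly$beta) > 0) {
    if (is.null(xreg_future)) {
      stop_input("fit uses regressors (",
                 paste(sfit$xreg_names, collapse = ", "),
                 "); xreg_future is required")
    }
    xreg_future <- as.matrix(xreg_future)
    if (nrow(xreg_future) != horizon) {
      stop_input("xreg_future must have `horizon` rows")
    }
    xreg_future <- xreg_future[, sfit$xreg_names, drop = FALSE]
  }
  hist <- adjusted_history(sfit, poly)
  a <- -poly$ar[-1]                      # w_t = sum a_i w_{t-i} + MA part
  m <- poly$ma[-1]
  np <- length(a); nq <- length(m)
  k <- as.integer(horizon)
  sigma <- sqrt(sfit$sigma2)
  W <- matrix(0, B, np + k)
  if (np > 0) {
    W[, seq_len(np)] <- matrix(rep(tail(hist$w, np), each = B), B, np)
  }
  E <- matrix(0, B, nq + k)
  if (nq > 0) {
    E[, seq_len(nq)] <- matrix(rep(tail(hist$e, nq), each = B), B, nq)
  }
  with_seed(seed, {
    innov <- matrix(rnorm(B * k, 0, sigma), B, k)
    for (h in seq_len(k)) {
      wcol <- np + h
      ecol <- nq + h
      E[, ecol] <- innov[, h]
      val <- innov[, h]
      if (np > 0) {
        val <- val + W[, wcol - seq_len(np), drop = FALSE] %*% a
      }
      if (nq > 0) {
        val <- val + E[, ecol - seq_len(nq), drop = FALSE] %*% m
      }
      W[, wcol] <- val
    }
  })
  paths <- W[, np + seq_len(k), drop = FALSE]
  drift <- rep(poly$mu, k)
  if (length(poly$beta) > 0) {
    drift <- drift + as.numeric(xreg_future %*% poly$beta)
  }
  paths <- sweep(paths, 2, drift, "+")
  M <- rowMeans(paths)
  structure(
    list(M = M, m_hat = mean(M), s_hat = sd(M), k = k, B = B,
         seed = seed, paths = if (keep_paths) paths else NULL),
    class = "counterfactual_summary"
  )
}

#' @export
print.counterfactual_summary <- function(x, ...) {
  cat(sprintf("<counterfactual_summary> k = %d, B = %d, m_hat = %.4f, s_hat = %.4f\n",
              x$k, x$B, x$m_hat, x$s_hat))
  if (!is.null(x$observed_mean)) {
    cat(sprintf("  observed mean = %.4f, Z = %.3f, %d%% CI [%.4f, %.4f], p = %.4g\n",
                x$observed_mean, x$Z, round(100 * (1 - x$alpha)),
                x$ci[1], x$ci[2], x$p.value))
  }
  invisible(x)
}
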