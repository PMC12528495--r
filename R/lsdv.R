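#' Build a monthly panel design for the fixed-effects regression
#'
#' Aligns monthly community outcomes with platform-wide moderation-intensity
#' predictors: transparency counts at month t-1 predict outcomes at month t
#' (a one-month lag guarding against enforcement intensity responding to
#' contemporaneous misinformation), and a first-order lagged dependent
#' variable captures autoregression. The first usable month drops rows
#' lacking either lag. With predictors spanning July 2020 - September 2022,
#' outcome rows span August 2020 - October 2022.
#'
#' @param monthly monthly measure panel (`community`, `month`, `measure`,
#'   `value`) from [monthly_aggregate()] or
#'   `build_measures(..., period = "month")`.
#' @param transparency transparency table (`month`, `content_removed`,
#'   `accounts_suspended`), months `YYYY-MM` and contiguous.
#' @param measure which measure's values become the outcome.
#' @param scale_per_thousand divide transparency counts by 1000 for
#'   conditioning (recorded in the attribute `scaling`).
#' @return An object of class `panel_design`: data.frame `community`,
#'   `month`, `y`, `y_lag`, `content_removed`, `accounts_suspended` (both
#'   lagged one month), with metadata attributes.
#' @export
build_panel <- function(monthly, transparency, measure = "content_logit",
                        scale_per_thousand = FALSE) {
  assert_columns(monthly, c("community", "month", "measure", "value"),
                 "monthly panel")
  assert_columns(transparency,
                 c("month", "content_removed", "accounts_suspended"),
                 "transparency table")
  tm <- transparency$month
  expect <- month_key_seq(min(tm), max(tm))
  missing <- setdiff(expect, tm)
  if (length(missing) > 0) {
    stop_input("transparency table has gap(s): missing month(s) ",
               paste(missing, collapse = ", "))
  }
  dat <- monthly[monthly$measure == measure, ]
  if (nrow(dat) == 0) stop_input("measure ", measure, " not in monthly panel")
  scl <- if (scale_per_thousand) 1000 else 1
  # predictors observed at t-1 predict outcomes at t
  pred <- data.frame(
    month = vapply(tm, function(m) {
      format(seq(as.Date(paste0(m, "-01")), by = "month",
                 length.out = 2)[2], "%Y-%m")
    }, character(1)),
    content_removed = transparency$content_removed / scl,
    accounts_suspended = transparency$accounts_suspended / scl,
    stringsAsFactors = FALSE
  )
  dat <- dat[order(dat$community, dat$month), ]
  dat$y_lag <- ave(dat$value, dat$community,
                   FUN = function(v) c(NA, head(v, -1)))
  panel <- merge(dat, pred, by = "month")
  panel <- panel[!is.na(panel$y_lag), ]
  panel <- data.frame(community = panel$community, month = panel$month,
                      y = panel$value, y_lag = panel$y_lag,
                      content_removed = panel$content_removed,
                      accounts_suspended = panel$accounts_suspended,
                      stringsAsFactors = FALSE)
  panel <- panel[order(panel$community, panel$month), ]
  rownames(panel) <- NULL
  structure(panel, class = c("panel_design", "data.frame"),
            measure = measure,
            scaling = if (scale_per_thousand) "per_thousand" else "raw")
}

#' Fit the least squares dummy variable (LSDV) fixed-effects model
#'
#' Regresses the monthly outcome on the lagged outcome, the two lagged
#' moderation-intensity predictors, a dummy for each community (one
#' reference community dropped to avoid the dummy trap), and optionally the
#' two-way interactions between each predictor and each community dummy.
#' Standard errors are heteroskedasticity- and autocorrelation-consistent
#' (Newey-West kernel HAC); the default lag length is the Newey-West
#' automatic rule `floor(4 * (T/100)^(2/9))` with T the months per
#' community. All reported tests are two-sided.
#'
#' @param panel a `panel_design` from [build_panel()].
#' @param hac_lags `"auto"` or a non-negative integer.
#' @param interactions include community x predictor interactions.
#' @param lagged_dv include the lagged dependent variable.
#' @return An object of class `lsdv_fit`: the `lm` fit, the HAC coefficient
#'   table (estimate, HAC SE, t, two-sided p), per-community residual
#'   series, reference community, and HAC metadata.
#' @export
fit_lsdv <- function(panel, hac_lags = "auto", interactions = TRUE,
                     lagged_dv = TRUE) {
  assert_columns(panel, c("community", "month", "y", "y_lag",
                          "content_removed", "accounts_suspended"), "panel")
  measure <- attr(panel, "measure")
  panel <- as.data.frame(panel)
  panel$community <- factor(panel$community)
  ref <- levels(panel$community)[1]
  for (v in c("content_removed", "accounts_suspended")) {
    if (var(panel[[v]]) == 0) {
      stop_input("rank deficiency: predictor '", v, "' has zero variance")
    }
  }
  rhs <- c(if (lagged_dv) "y_lag",
           "content_removed", "accounts_suspended", "community",
           if (interactions) c("community:content_removed",
                               "community:accounts_suspended"))
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- lm(fml, data = panel)
  alias <- is.na(coef(fit))
  if (any(alias)) {
    stop_input("rank deficiency: collinear column(s): ",
               paste(names(coef(fit))[alias], collapse = ", "))
  }
  months_per_comm <- length(unique(panel$month))
  lag_len <- if (identical(hac_lags, "auto")) {
    floor(4 * (months_per_comm / 100)^(2 / 9))
  } else {
    as.integer(hac_lags)
  }
  vc <- sandwich::NeweyWest(fit, lag = lag_len, prewhite = FALSE,
                            adjust = TRUE)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  coef_table <- data.frame(
    term = rownames(ct),
    estimate = ct[, 1], hac_se = ct[, 2],
    t = ct[, 3], p = ct[, 4],
    row.names = NULL, stringsAsFactors = FALSE
  )
  resid_by_comm <- split(residuals(fit), panel$community)
  structure(
    list(model = fit, coef = coef_table, vcov = vc,
         residuals_by_community = resid_by_comm,
         reference_community = ref, hac_lags = lag_len,
         interactions = interactions, lagged_dv = lagged_dv,
         measure = measure),
    class = "lsdv_fit"
  )
}

#' @export
print.lsdv_fit <- function(x, ...) {
  cat("<lsdv_fit>", nrow(x$coef), "coefficients, HAC lags =", x$hac_lags,
      ", reference community =", x$reference_community, "\n")
  main <- x$coef[x$coef$term %in% c("(Intercept)", "y_lag",
                                    "content_removed",
                                    "accounts_suspended"), ]
  print(main, digits = 4)
  invisible(x)
}

#' Residual stationarity diagnostics for an LSDV fit
#'
#' Runs the augmented Dickey-Fuller test on each community's residual
#' series. Series shorter than 12 months or degenerate (constant) are
#' reported as inconclusive rather than failed. The pooled verdict is
#' `"stationary"` when more than half of the testable series reject the
#' unit root at the 5% level, `"non-stationary"` when they do not, and
#' `"inconclusive"` when no series is testable.
#'
#' @param fit an `lsdv_fit`.
#' @return list of class `adf_report`: per-community data.frame
#'   (`community`, `statistic`, `p`, `verdict`) and `pooled` verdict.
#' @export
residual_stationarity <- function(fit) {
  if (!inherits(fit, "lsdv_fit")) stop_input("fit must be an lsdv_fit")
  rows <- lapply(names(fit$residuals_by_community), function(cc) {
    r <- fit$residuals_by_community[[cc]]
    a <- adf_test(r)
    data.frame(community = cc, statistic = a$statistic, p = a$p.value,
               verdict = a$verdict, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  testable <- df$verdict != "inconclusive"
  pooled <- if (!any(testable)) {
    "inconclusive"
  } else if (mean(df$verdict[testable] == "stationary") > 0.5) {
    "stationary"
  } else {
    "non-stationary"
  }
  structure(list(by_community = df, pooled = pooled), class = "adf_report")
}

#' @export
print.adf_report <- function(x, ...) {
  cat("<adf_report> pooled verdict:", x$pooled, "\n")
  print(x$by_community, digits = 3)
  invisible(x)
}
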