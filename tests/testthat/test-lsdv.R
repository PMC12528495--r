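# synthetic monthly panel generated from known LSDV coefficients
sim_panel <- function(seed, n_comm = 3, n_months = 28, rho = 0.3,
                      b_content = -0.5, b_susp = 0.2, sd_noise = 0.05,
                      offsets = NULL, scale = 1000) {
  set.seed(seed)
  months_pred <- month_key_seq("2020-07",
                               format(seq(as.Date("2020-07-01"),
                                          by = "month",
                                          length.out = n_months)[n_months],
                                      "%Y-%m"))
  transparency <- data.frame(
    month = months_pred,
    content_removed = rpois(n_months, 4) * scale / 4,
    accounts_suspended = rpois(n_months, 3) * scale / 30,
    stringsAsFactors = FALSE)
  offsets <- offsets %||% seq(-1, 1, length.out = n_comm)
  comms <- sprintf("c%02d", seq_len(n_comm))
  months_out <- month_key_seq("2020-07",
                              format(seq(as.Date("2020-07-01"), by = "month",
                                         length.out = n_months + 1)[n_months + 1],
                                     "%Y-%m"))
  rows <- list()
  for (i in seq_len(n_comm)) {
    y <- numeric(n_months + 1)
    y[1] <- offsets[i]
    for (t in 2:(n_months + 1)) {
      # outcome at month t is driven by transparency at month t-1
      y[t] <- offsets[i] + rho * y[t - 1] +
        b_content * transparency$content_removed[t - 1] / scale +
        b_susp * transparency$accounts_suspended[t - 1] / scale +
        rnorm(1, 0, sd_noise)
    }
    rows[[i]] <- data.frame(community = comms[i], month = months_out,
                            measure = "content_logit", value = y,
                            stringsAsFactors = FALSE)
  }
  list(monthly = do.call(rbind, rows), transparency = transparency,
       truth = c(y_lag = rho, content_removed = b_content / scale,
                 accounts_suspended = b_susp / scale))
}

test_that("panel rows align outcomes at t with predictors at t-1", {
  sim <- sim_panel(1, n_comm = 2, n_months = 27)  # Jul 2020 .. Sep 2022
  pan <- build_panel(sim$monthly, sim$transparency)
  expect_equal(min(pan$month), "2020-08")
  expect_equal(max(pan$month), "2022-10")
  expect_equal(nrow(pan), 2 * 27)
  # the predictor stored at month t is the transparency count of t-1
  pick <- pan[pan$community == "c01" & pan$month == "2021-03", ]
  expect_equal(pick$content_removed,
               sim$transparency$content_removed[
                 sim$transparency$month == "2021-02"])
  # and the lagged outcome is last month's outcome
  prev <- sim$monthly[sim$monthly$community == "c01" &
                        sim$monthly$month == "2021-02", ]
  expect_equal(pick$y_lag, prev$value)
})

test_that("a 2 x 12 usable panel has 24 rows and survives row shuffling", {
  sim <- sim_panel(2, n_comm = 2, n_months = 12)
  pan <- build_panel(sim$monthly, sim$transparency)
  expect_equal(nrow(pan), 24)
  shuffled <- sim$monthly[sample(nrow(sim$monthly)), ]
  pan2 <- build_panel(shuffled, sim$transparency)
  expect_equal(pan, pan2, ignore_attr = TRUE)
})

test_that("a gap in the transparency months is named in the error", {
  sim <- sim_panel(3, n_months = 10)
  tr <- sim$transparency[-4, ]
  expect_error(build_panel(sim$monthly, tr),
               sim$transparency$month[4])
})

test_that("known coefficients are recovered within two HAC standard errors", {
  hits <- vapply(1:100, function(s) {
    sim <- sim_panel(100 + s, n_comm = 3, n_months = 27)
    pan <- build_panel(sim$monthly, sim$transparency)
    fit <- fit_lsdv(pan, interactions = FALSE)
    vapply(names(sim$truth), function(tm) {
      row <- fit$coef[fit$coef$term == tm, ]
      abs(row$estimate - sim$truth[[tm]]) <= 2 * row$hac_se
    }, logical(1))
  }, logical(3))
  # each coefficient lands within two HAC SEs in at least 90% of seeds
  expect_true(all(rowMeans(hits) >= 0.9))
})

test_that("degenerate designs raise rank-deficiency errors", {
  sim <- sim_panel(4, n_months = 15)
  pan <- build_panel(sim$monthly, sim$transparency)
  pan$content_removed <- 1
  expect_error(fit_lsdv(pan), "zero variance")
  pan2 <- build_panel(sim$monthly, sim$transparency)
  pan2$accounts_suspended <- pan2$content_removed
  expect_error(fit_lsdv(pan2), "collinear")
})

test_that("HAC standard errors track classical OLS under i.i.d. errors", {
  sim <- sim_panel(5, n_comm = 4, n_months = 40, rho = 0, sd_noise = 0.3)
  pan <- build_panel(sim$monthly, sim$transparency)
  fit <- fit_lsdv(pan, hac_lags = 0, interactions = FALSE,
                  lagged_dv = FALSE)
  ols <- summary(fit$model)$coefficients
  for (tm in c("content_removed", "accounts_suspended")) {
    hac <- fit$coef$hac_se[fit$coef$term == tm]
    cls <- ols[tm, "Std. Error"]
    expect_lt(abs(hac - cls) / cls, 0.25)
  }
})

test_that("LSDV equals the within estimator when the design is static", {
  sim <- sim_panel(6, n_comm = 4, n_months = 30, rho = 0)
  pan <- build_panel(sim$monthly, sim$transparency)
  fit <- fit_lsdv(pan, interactions = FALSE, lagged_dv = FALSE)
  # within transformation: demean y and predictors by community
  dm <- function(v) v - ave(v, pan$community)
  wfit <- lm(dm(pan$y) ~ 0 + dm(pan$content_removed) +
               dm(pan$accounts_suspended))
  expect_equal(
    fit$coef$estimate[fit$coef$term == "content_removed"],
    unname(coef(wfit)[1]), tolerance = 1e-8)
  expect_equal(
    fit$coef$estimate[fit$coef$term == "accounts_suspended"],
    unname(coef(wfit)[2]), tolerance = 1e-8)
})

test_that("lagged-DV bias shrinks as the panel grows", {
  est_rho <- function(n_months, seeds) {
    vapply(seeds, function(s) {
      sim <- sim_panel(500 + s, n_comm = 3, n_months = n_months,
                       sd_noise = 0.2)
      pan <- build_panel(sim$monthly, sim$transparency)
      fit <- fit_lsdv(pan, interactions = FALSE)
      fit$coef$estimate[fit$coef$term == "y_lag"]
    }, numeric(1))
  }
  bias_short <- mean(est_rho(27, 1:30)) - 0.3
  bias_long <- mean(est_rho(270, 1:10)) - 0.3
  expect_lt(abs(bias_long), abs(bias_short))
  expect_lt(abs(bias_long), 0.03)
})

test_that("interaction terms expose community-specific predictor responses", {
  sim <- sim_panel(7, n_comm = 3, n_months = 30)
  pan <- build_panel(sim$monthly, sim$transparency)
  fit <- fit_lsdv(pan, interactions = TRUE)
  expect_true(any(grepl("content_removed:community", fit$coef$term)))
  expect_true(any(grepl("accounts_suspended:community", fit$coef$term)))
  expect_equal(fit$reference_community, "c01")
})

test_that("residual stationarity verdicts separate noise from random walks", {
  sim <- sim_panel(8, n_comm = 4, n_months = 100, rho = 0, sd_noise = 0.3)
  pan <- build_panel(sim$monthly, sim$transparency)
  fit <- fit_lsdv(pan, interactions = FALSE, lagged_dv = FALSE)
  rep <- residual_stationarity(fit)
  expect_equal(rep$pooled, "stationary")

  # replace outcomes by random walks: residuals inherit the unit root
  set.seed(9)
  rw <- sim
  rw$monthly$value <- ave(rnorm(nrow(rw$monthly), 0, 1),
                          rw$monthly$community, FUN = cumsum)
  pan_rw <- build_panel(rw$monthly, rw$transparency)
  fit_rw <- fit_lsdv(pan_rw, interactions = FALSE, lagged_dv = FALSE)
  expect_equal(residual_stationarity(fit_rw)$pooled, "non-stationary")
})

test_that("short and constant series are inconclusive, not failures", {
  expect_equal(adf_test(rnorm(8))$verdict, "inconclusive")
  expect_equal(adf_test(rep(2, 30))$verdict, "inconclusive")
})
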