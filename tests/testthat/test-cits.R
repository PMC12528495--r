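# minimal hand-built counterfactual summary for statistic-level tests
fake_cf <- function(m_hat, s_hat, k = 10, B = 100) {
  structure(list(M = numeric(B), m_hat = m_hat, s_hat = s_hat, k = k, B = B,
                 seed = 1L, paths = NULL),
            class = "counterfactual_summary")
}

test_that("fixed orders are honoured and fits expose diagnostics", {
  set.seed(1)
  y <- as.numeric(arima.sim(list(ar = 0.5), 200))
  sf <- fit_pre_period(y, order = c(1, 0, 0), period = 1)
  expect_equal(sf$order, c(1, 0, 0))
  expect_equal(sf$seasonal, c(0, 0, 0))
  expect_true(is.finite(sf$aic))
  expect_true(sf$ljung_box_p > 0 && sf$ljung_box_p <= 1)
  expect_error(fit_pre_period(c(y, NA)), "NA")
})

test_that("order search lands near the null model on white noise", {
  set.seed(2)
  wn <- rnorm(300)
  sf <- fit_pre_period(wn, order = "auto", period = 1)
  expect_lte(sum(sf$order[c(1, 3)]), 4)
  expect_equal(sf$sigma2, var(wn), tolerance = 0.15)
})

test_that("the AR(1) coefficient is recovered across seeds", {
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    y <- as.numeric(arima.sim(list(ar = 0.6), 300))
    sf <- fit_pre_period(y, order = c(1, 0, 0), period = 1)
    coef(sf$fit)[["ar1"]] - 0.6
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.15)
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("constant phase dummies are dropped before fitting", {
  set.seed(3)
  y <- rnorm(120)
  x <- cbind(live = c(rep(0, 60), rep(1, 60)), dead = rep(0, 120))
  sf <- fit_pre_period(y, order = c(0, 0, 0), period = 1, xreg = x)
  expect_equal(sf$xreg_names, "live")
  expect_equal(sf$dropped_regressors, "dead")
})

test_that("counterfactual simulation matches the i.i.d. closed form", {
  set.seed(4)
  mu <- 5; sigma <- 2; n <- 400
  y <- rnorm(n, mu, sigma)
  sf <- fit_pre_period(y, order = c(0, 0, 0), period = 1)
  k <- 25
  cf <- simulate_counterfactual(sf, horizon = k, B = 4000, seed = 7)
  expect_equal(cf$m_hat, mu, tolerance = 4 * sigma / sqrt(k * 4000) + 0.15)
  expect_equal(cf$s_hat, sigma / sqrt(k), tolerance = 0.05)
  # doubling B leaves m_hat within Monte-Carlo error
  cf2 <- simulate_counterfactual(sf, horizon = k, B = 8000, seed = 8)
  expect_lt(abs(cf2$m_hat - cf$m_hat), 3 * cf$s_hat / sqrt(4000) * 2)
})

test_that("simulation inputs are validated", {
  set.seed(5)
  sf <- fit_pre_period(rnorm(100), order = c(0, 0, 0), period = 1)
  expect_error(simulate_counterfactual(sf, horizon = 0), "horizon")
  expect_error(simulate_counterfactual(sf, horizon = 5, B = 1), "B")
  sfx <- fit_pre_period(rnorm(100), order = c(0, 0, 0), period = 1,
                        xreg = cbind(z = c(rep(0, 50), rep(1, 50))))
  expect_error(simulate_counterfactual(sfx, horizon = 5), "xreg_future")
})

test_that("simulation is reproducible from its seed", {
  set.seed(6)
  sf <- fit_pre_period(as.numeric(arima.sim(list(ar = 0.4), 150)),
                       order = c(1, 0, 0), period = 1)
  a <- simulate_counterfactual(sf, 20, B = 200, seed = 42)
  b <- simulate_counterfactual(sf, 20, B = 200, seed = 42)
  expect_identical(a$M, b$M)
})

test_that("the single-series Z behaves at its anchor points", {
  cf <- fake_cf(m_hat = 1, s_hat = 0.5, k = 4)
  z0 <- single_series_z(cf, rep(1, 4))
  expect_equal(z0$Z, 0)
  expect_equal(mean(z0$ci), 0)

  z196 <- single_series_z(cf, rep(1 + 1.96 * 0.5, 4))
  expect_equal(z196$Z, 1.96, tolerance = 1e-6)
  expect_lt(abs(z196$ci[1]), 1e-4)
  expect_equal(z196$z_crit, qnorm(0.975))

  expect_error(single_series_z(fake_cf(1, 0), rep(1, 10)),
               "undefined statistic")
  expect_error(single_series_z(cf, rep(1, 3)), "length")
})

test_that("the CI excludes zero exactly when |Z| exceeds its critical value", {
  set.seed(9)
  for (alpha in c(0.05, 0.01, 0.2)) {
    for (i in 1:200) {
      cf <- fake_cf(m_hat = rnorm(1), s_hat = runif(1, 0.01, 2), k = 5)
      obs <- rep(rnorm(1, cf$m_hat, 2 * cf$s_hat), 5)
      z <- single_series_z(cf, obs, alpha = alpha)
      expect_identical(abs(z$Z) > z$z_crit, z$ci[1] > 0 || z$ci[2] < 0)
    }
  }
})

complete_cf <- function(m_hat, s_hat, obs_mean, k = 6) {
  single_series_z(fake_cf(m_hat, s_hat, k), rep(obs_mean, k))
}

test_that("comparative Z contrasts deviations with summed variances", {
  tr <- complete_cf(0, 0.3, 0.6)   # deviation +0.6
  co <- complete_cf(0, 0.4, 0)     # deviation 0
  cmp <- comparative_z(tr, co, "content_logit")
  expect_equal(cmp$Z, 0.6 / sqrt(0.3^2 + 0.4^2))
  expect_equal(cmp$estimate, exp(0.6))
  expect_equal(cmp$scale, "odds_ratio")

  same <- comparative_z(complete_cf(1, 0.2, 1.5), complete_cf(2, 0.2, 2.5),
                        "content_logit")
  expect_equal(same$Z, 0)
  expect_equal(same$estimate, 1)

  # antisymmetry of the numerator under treated/comparator swap
  swapped <- comparative_z(co, tr, "content_logit")
  expect_equal(swapped$diff, -cmp$diff)
})

test_that("the printed denominator variant errors on non-positive variance", {
  tr <- complete_cf(0, 0.3, 0.5)
  co <- complete_cf(0, 0.4, 0)
  expect_error(comparative_z(tr, co, pooling = "as_printed"),
               "degenerate denominator")
  ok <- comparative_z(co, tr, pooling = "as_printed")
  expect_equal(ok$denom, sqrt(0.4^2 - 0.3^2))
  expect_error(comparative_z(tr, complete_cf(0, 0.4, 0, k = 9)),
               "mismatched horizons")
})

test_that("effects back-transform to their reporting scales", {
  expect_equal(effect_scale(0, "content_logit")$estimate, 1)
  expect_equal(effect_scale(log(2), "content_logit")$estimate, 2)
  expect_equal(effect_scale(log(1.4), "virality_log")$estimate, 1.4)
  expect_equal(effect_scale(log(1.4), "virality_log")$scale, "relative_risk")
  q <- effect_scale(-0.07, "quality_mean")
  expect_equal(q$estimate, -0.07)
  expect_equal(q$scale, "delta")
  expect_equal(effect_scale(0.3, "topic_logit_skepticism")$scale,
               "odds_ratio")
  expect_error(effect_scale(1, "unknown"), "measure_kind")
  # round trip on positive ratios
  for (r in c(0.33, 1, 1.4, 5.31)) {
    expect_equal(effect_scale(log(r), "content_logit")$estimate, r)
  }
})

test_that("phase dummies honour inclusive boundaries", {
  phases <- data.frame(phase = c("a", "b"),
                       start = as.Date(c("2020-01-01", "2020-01-11")),
                       end = as.Date(c("2020-01-10", "2020-01-20")))
  d <- phase_dummies(phases, as.Date("2020-01-01") + 0:19)
  expect_equal(sum(d[, "a"]), 10)
  expect_equal(sum(d[, "b"]), 10)
  expect_equal(unname(d[10, ]), c(1, 0))
  expect_equal(unname(d[11, ]), c(0, 1))
  bad <- data.frame(phase = "x", start = as.Date("2020-02-01"),
                    end = as.Date("2020-01-01"))
  expect_error(phase_dummies(bad, as.Date("2020-01-01")), "end date")
})

test_that("the default policy phase table is contiguous over the study window", {
  ph <- default_policy_phases()
  expect_equal(ph$start[1], as.Date("2020-02-07"))
  expect_equal(ph$start[ph$phase == "vaccine_misinfo_removal"],
               as.Date("2020-12-20"))
  expect_equal(ph$end[ph$phase == "clarifying_misleading_information"],
               as.Date("2020-12-19"))
  expect_equal(ph$start[ph$phase == "five_strikes"], as.Date("2021-03-01"))
  expect_equal(ph$end[ph$phase == "five_strikes"], as.Date("2022-11-22"))
  # the first twelve phases tile the span without gaps
  main <- ph[1:12, ]
  expect_equal(main$start[-1], main$end[-12] + 1)
})

test_that("run_cits wires fits, forecasts, and contrasts end to end", {
  set.seed(10)
  start <- as.Date("2020-02-07")
  days <- start + 0:149
  mk <- function(shift) {
    base <- as.numeric(arima.sim(list(ar = 0.5), 150, sd = 0.1))
    base + c(rep(0, 120), rep(shift, 30))
  }
  panel <- rbind(
    data.frame(community = "anti", date = days, measure = "content_logit",
               value = mk(0.7), n = 1),
    data.frame(community = "pro", date = days, measure = "content_logit",
               value = mk(0), n = 1))
  phases <- data.frame(phase = "policy", start = start + 120,
                       end = start + 149)
  pairs <- data.frame(treated = "anti", comparator = "pro")
  eff <- run_cits(panel, pairs, phases = phases, eval_phases = "policy",
                  B = 400, seed = 2, order = c(1, 0, 0), period = 1)
  expect_equal(nrow(eff), 1)
  expect_equal(eff$scale, "odds_ratio")
  expect_equal(eff$k, 30)
  expect_gt(eff$z, 2)
  expect_equal(eff$estimate, exp(0.7), tolerance = 0.25)
  # swapping the pair negates the comparative deviation
  eff_sw <- run_cits(panel, data.frame(treated = "pro", comparator = "anti"),
                     phases = phases, eval_phases = "policy", B = 400,
                     seed = 2, order = c(1, 0, 0), period = 1)
  expect_equal(log(eff_sw$estimate), -log(eff$estimate), tolerance = 0.15)
  # a missing comparator is skipped with a warning
  expect_warning(
    expect_error(
      run_cits(panel, data.frame(treated = "anti", comparator = "ghost"),
               phases = phases, eval_phases = "policy", B = 50,
               order = c(1, 0, 0), period = 1),
      "no CITS cells"),
    "comparator")
})
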