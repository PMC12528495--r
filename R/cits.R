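#' Default platform policy-phase table
#'
#' The platform's announced moderation measures over 2020-2022, each realised
#' as a binary dummy regressor with inclusive start and end dates: the
#' sequence of COVID-19 information measures through 2020, the vaccine
#' misinformation removal policy beginning Sunday 2020-12-20, the mass
#' deplatforming of 2021-01-08, the "five strikes" policy from 2021-03-01
#' through 2022-11-22, the account reinstatement window, and the suspension
#' of the medical misinformation policy (the last two overlap).
#'
#' @return data.frame `phase`, `start`, `end` (Date, both inclusive).
#' @export
default_policy_phases <- function() {
  data.frame(
    phase = c("initial_period",
              "search_prompt_event_page",
              "updated_policies_automated_tech",
              "broadened_definition_of_harm",
              "updated_ad_policy",
              "unverified_claims_violate_policies",
              "new_labels_warning_messages",
              "covid19_tab_in_explore",
              "clarifying_misleading_information",
              "vaccine_misinfo_removal",
              "mass_deplatforming",
              "five_strikes",
              "president_reinstated",
              "medical_misinfo_policy_suspended"),
    start = as.Date(c("2020-02-07", "2020-03-04", "2020-03-16", "2020-03-27",
                      "2020-04-02", "2020-04-22", "2020-05-11", "2020-05-18",
                      "2020-07-14", "2020-12-20", "2021-01-08", "2021-03-01",
                      "2022-11-18", "2022-11-23")),
    end = as.Date(c("2020-03-03", "2020-03-15", "2020-03-26", "2020-04-01",
                    "2020-04-21", "2020-05-10", "2020-05-17", "2020-07-13",
                    "2020-12-19", "2021-01-07", "2021-02-28", "2022-11-22",
                    "2022-12-17", "2022-12-17")),
    stringsAsFactors = FALSE
  )
}

#' Read a phase-configuration table from YAML
#'
#' YAML rows `phase`, `start`, `end`; see [default_policy_phases()] for the
#' default table.
#'
#' @param path YAML file path.
#' @return data.frame `phase`, `start`, `end`.
#' @export
read_phase_table <- function(path) {
  rows <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(phase = r$phase, start = as.Date(r$start),
               end = as.Date(r$end), stringsAsFactors = FALSE)
  }))
  validate_phases(df)
  df
}

validate_phases <- function(phases) {
  assert_columns(phases, c("phase", "start", "end"), "phase table")
  if (any(phases$end < phases$start)) {
    stop_input("phase table: end date before start date for ",
               paste(phases$phase[phases$end < phases$start], collapse = ", "))
  }
  invisible(phases)
}

#' Phase dummy design matrix over a date vector
#'
#' One 0/1 column per phase, 1 on dates inside the phase's inclusive
#' \[start, end\] window.
#'
#' @param phases phase data.frame (`phase`, `start`, `end`).
#' @param dates `Date` vector.
#' @return numeric matrix, `length(dates)` rows, one named column per phase.
#' @export
phase_dummies <- function(phases, dates) {
  validate_phases(phases)
  dates <- as.Date(dates)
  mat <- vapply(seq_len(nrow(phases)), function(i) {
    as.numeric(dates >= phases$start[i] & dates <= phases$end[i])
  }, numeric(length(dates)))
  mat <- matrix(mat, nrow = length(dates))
  colnames(mat) <- phases$phase
  mat
}

#' Complete a counterfactual summary against observed post-policy data
#'
#' Computes the observed post-period mean, the standardised difference
#' `Z = (mean(y) - m_hat) / s_hat`, its two-sided normal p-value, and the
#' confidence interval `mean(y) - m_hat +/- z_crit * s_hat` with
#' `z_crit = N(1 + alpha/2)` (1.96 at alpha = 0.05). By construction the CI
#' excludes 0 exactly when `|Z| > z_crit`.
#'
#' @param cf `counterfactual_summary` from [simulate_counterfactual()].
#' @param observed numeric vector of observed post-period values, length `k`.
#' @param alpha two-sided type-I error rate (default 0.05).
#' @return The completed `counterfactual_summary` with `observed_mean`,
#'   `diff`, `Z`, `ci`, `p.value`, `alpha`, `z_crit`.
#' @export
single_series_z <- function(cf, observed, alpha = 0.05) {
  if (!inherits(cf, "counterfactual_summary")) {
    stop_input("cf must be a counterfactual_summary")
  }
  observed <- as.numeric(observed)
  if (length(observed) != cf$k) {
    stop_input("observed series length (", length(observed),
               ") must equal the forecast horizon k (", cf$k, ")")
  }
  if (anyNA(observed)) stop_input("observed series contains NA")
  if (!is.finite(cf$s_hat) || cf$s_hat <= 0) {
    stop_input("undefined statistic: s_hat is zero (degenerate forecast ",
               "distribution); Z cannot be computed")
  }
  z_crit <- qnorm(1 - alpha / 2)
  obs_mean <- mean(observed)
  diff <- obs_mean - cf$m_hat
  Z <- diff / cf$s_hat
  cf$observed_mean <- obs_mean
  cf$diff <- diff
  cf$Z <- Z
  cf$alpha <- alpha
  cf$z_crit <- z_crit
  cf$ci <- c(diff - z_crit * cf$s_hat, diff + z_crit * cf$s_hat)
  cf$p.value <- 2 * pnorm(-abs(Z))
  cf
}

#' Back-transform an average daily difference to its reporting scale
#'
#' Logit-scale measures (content proportions, topic shares) exponentiate to
#' odds ratios; the log virality measure exponentiates to a relative risk;
#' domain quality is reported as an untransformed additive difference.
#' CI endpoints transform monotonically the same way.
#'
#' @param diff average daily difference (and optionally CI endpoints) on the
#'   model scale.
#' @param measure_kind `"content_logit"`, `"virality_log"`,
#'   `"quality_mean"`, or `"topic_logit_<group>"`.
#' @return list `scale` (`"odds_ratio"`, `"relative_risk"`, or `"delta"`)
#'   and `estimate` (transformed values, same shape as `diff`).
#' @export
#' @examples
#' effect_scale(log(2), "content_logit")$estimate  # 2
#' effect_scale(-0.07, "quality_mean")$estimate    # -0.07
effect_scale <- function(diff, measure_kind) {
  if (grepl("^(content_logit|topic_logit)", measure_kind)) {
    list(scale = "odds_ratio", estimate = exp(diff))
  } else if (measure_kind == "virality_log") {
    list(scale = "relative_risk", estimate = exp(diff))
  } else if (measure_kind == "quality_mean") {
    list(scale = "delta", estimate = diff)
  } else {
    stop_input("unknown measure_kind: ", measure_kind)
  }
}

#' Comparative Z statistic for a treated/comparator pair
#'
#' Contrasts the treated community's deviation from its counterfactual with
#' the comparator's: the numerator is
#' `(mean(y_treated) - m_hat_treated) - (mean(y_comparator) - m_hat_comparator)`.
#' With `pooling = "sum"` (default) the denominator is
#' `sqrt(s_treated^2 + s_comparator^2)`, the standard deviation of a
#' difference of independent estimates. `pooling = "as_printed"` instead
#' uses `sqrt(s_treated^2 - s_comparator^2)` and raises an explicit
#' degenerate-denominator error when the difference is not positive.
#'
#' @param treated,comparator completed `counterfactual_summary` objects
#'   (via [single_series_z()]) on identical calendar horizons.
#' @param measure_kind reporting scale selector, see [effect_scale()].
#' @param pooling `"sum"` or `"as_printed"`.
#' @param alpha two-sided type-I error rate.
#' @return An object of class `comparative_effect`: `Z`, `p.value`, `diff`
#'   (model scale), `scale`, `estimate`, `ci` (reporting scale), `pooling`,
#'   plus the two summaries.
#' @export
comparative_z <- function(treated, comparator,
                          measure_kind = "content_logit",
                          pooling = c("sum", "as_printed"),
                          alpha = 0.05) {
  pooling <- match.arg(pooling)
  for (cf in list(treated, comparator)) {
    if (!inherits(cf, "counterfactual_summary") || is.null(cf$observed_mean)) {
      stop_input("treated and comparator must be completed ",
                 "counterfactual_summary objects (run single_series_z first)")
    }
  }
  if (treated$k != comparator$k) {
    stop_input("mismatched horizons: treated k = ", treated$k,
               ", comparator k = ", comparator$k)
  }
  num <- treated$diff - comparator$diff
  v <- if (pooling == "sum") {
    treated$s_hat^2 + comparator$s_hat^2
  } else {
    treated$s_hat^2 - comparator$s_hat^2
  }
  if (!is.finite(v) || v <= 0) {
    stop_input("degenerate denominator: pooled variance is ", signif(v, 4),
               " under pooling='", pooling, "'")
  }
  denom <- sqrt(v)
  Z <- num / denom
  z_crit <- qnorm(1 - alpha / 2)
  ci_raw <- c(num - z_crit * denom, num + z_crit * denom)
  eff <- effect_scale(num, measure_kind)
  ci <- effect_scale(ci_raw, measure_kind)$estimate
  structure(
    list(Z = Z, p.value = 2 * pnorm(-abs(Z)), diff = num, denom = denom,
         scale = eff$scale, estimate = eff$estimate, ci = ci,
         pooling = pooling, alpha = alpha, z_crit = z_crit,
         treated = treated, comparator = comparator,
         measure_kind = measure_kind),
    class = "comparative_effect"
  )
}

#' @export
print.comparative_effect <- function(x, ...) {
  cat(sprintf("<comparative_effect> %s = %.3f [%.3f, %.3f], Z = %.3f, p = %.4g (pooling=%s)\n",
              x$scale, x$estimate, x$ci[1], x$ci[2], x$Z, x$p.value,
              x$pooling))
  invisible(x)
}

panel_series <- function(panel, community, measure) {
  rows <- panel[panel$community == community & panel$measure == measure, ]
  rows <- rows[order(rows$date), ]
  rows
}

#' Run the full comparative interrupted time series analysis
#'
#' For every treated/comparator pair, evaluated phase, and measure: fits a
#' pre-period SARIMAX (pre-period = all days strictly before the phase
#' start) with earlier phases as dummy regressors, simulates `B`
#' counterfactual forecast paths over the phase, completes single-series Z
#' statistics for treated and comparator, and forms the comparative Z and
#' back-transformed effect with CI. The evaluated phase's own dummy is held
#' at 0 over the horizon (it is all-zero in the pre-period and so never
#' enters the fit); earlier phases keep their actual dummy values.
#'
#' @param panel imputed daily measure panel (`community`, `date`, `measure`,
#'   `value`).
#' @param pairs data.frame `treated`, `comparator` of community ids.
#' @param phases phase table (`phase`, `start`, `end`); default
#'   [default_policy_phases()].
#' @param eval_phases character vector of phase names to evaluate.
#' @param measures measures to analyse; default all in the panel.
#' @param alpha type-I error rate; with `correction = "bonferroni"` the
#'   per-test alpha is divided by the number of pairs within each
#'   measure-phase cell.
#' @param B simulated forecast paths per fit.
#' @param seed root seed; each (pair, phase, measure) cell draws its own
#'   substream.
#' @param pooling comparative denominator rule, see [comparative_z()].
#' @param order,seasonal,period SARIMAX order controls, see
#'   [fit_pre_period()].
#' @param correction `"none"` or `"bonferroni"`.
#' @return data.frame with one row per (pair, phase, measure): single-series
#'   treated and comparator Z/p, comparative Z/p, and the back-transformed
#'   effect estimate with CI (`scale`, `estimate`, `lo`, `hi`).
#' @export
run_cits <- function(panel, pairs, phases = default_policy_phases(),
                     eval_phases = c("vaccine_misinfo_removal", "five_strikes"),
                     measures = NULL, alpha = 0.05, B = 1000, seed = 1L,
                     pooling = c("sum", "as_printed"), order = "auto",
                     seasonal = c(0, 0, 0), period = 7,
                     correction = c("none", "bonferroni")) {
  pooling <- match.arg(pooling)
  correction <- match.arg(correction)
  assert_columns(panel, c("community", "date", "measure", "value"), "panel")
  assert_columns(pairs, c("treated", "comparator"), "pairs")
  validate_phases(phases)
  panel$date <- as.Date(panel$date)
  measures <- measures %||% unique(panel$measure)
  alpha_eff <- if (correction == "bonferroni") alpha / nrow(pairs) else alpha
  out <- list()
  for (ph in eval_phases) {
    prow <- phases[phases$phase == ph, ]
    if (nrow(prow) != 1) stop_input("unknown evaluation phase: ", ph)
    for (i in seq_len(nrow(pairs))) {
      tr <- pairs$treated[i]
      co <- pairs$comparator[i]
      for (ms in measures) {
        tr_series <- panel_series(panel, tr, ms)
        co_series <- panel_series(panel, co, ms)
        if (nrow(co_series) == 0) {
          warning("comparator ", co, " missing for measure ", ms,
                  "; pair skipped")
          next
        }
        if (nrow(tr_series) == 0) {
          warning("treated ", tr, " missing for measure ", ms,
                  "; pair skipped")
          next
        }
        cell <- tryCatch(
          cits_cell(tr_series, co_series, prow, phases, ms, alpha_eff, B,
                    substream_seed(seed, "cits", ph, tr, co, ms),
                    pooling, order, seasonal, period),
          error = function(e) {
            warning("cell (", tr, " vs ", co, ", ", ph, ", ", ms,
                    ") failed: ", conditionMessage(e))
            NULL
          })
        if (is.null(cell)) next
        out[[length(out) + 1L]] <- data.frame(
          treated = tr, comparator = co, phase = ph, measure = ms,
          n_pre = cell$n_pre, k = cell$k,
          z_treated = cell$treated$Z, p_treated = cell$treated$p.value,
          effect_treated = cell$effect_treated$estimate,
          treated_lo = cell$effect_treated_ci[1],
          treated_hi = cell$effect_treated_ci[2],
          z_comparator = cell$comparator$Z,
          p_comparator = cell$comparator$p.value,
          scale = cell$comp$scale,
          estimate = cell$comp$estimate,
          lo = cell$comp$ci[1], hi = cell$comp$ci[2],
          z = cell$comp$Z, p = cell$comp$p.value,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    stop_input("no CITS cells could be evaluated")
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  attr(res, "alpha_effective") <- alpha_eff
  attr(res, "pooling") <- pooling
  attr(res, "correction") <- correction
  res
}

cits_cell <- function(tr_series, co_series, prow, phases, measure_kind,
                      alpha, B, seed, pooling, order, seasonal, period) {
  dates <- tr_series$date
  if (!identical(as.character(dates), as.character(co_series$date))) {
    stop_input("treated and comparator series cover different dates")
  }
  pre_idx <- which(dates < prow$start)
  post_idx <- which(dates >= prow$start & dates <= prow$end)
  if (length(pre_idx) < 30) {
    stop_input("pre-period too short (", length(pre_idx), " days)")
  }
  if (length(post_idx) < 2) stop_input("evaluation phase not in panel span")
  k <- length(post_idx)
  dmat <- phase_dummies(phases, dates)
  # the evaluated policy's dummy is the counterfactual's zero column
  dmat[, prow$phase] <- 0
  # the phase in force on the eve of the policy is the reference regime:
  # its level is absorbed by the intercept, so the counterfactual horizon
  # (all dummies zero) continues the status quo
  ref <- colnames(dmat)[dmat[max(pre_idx), ] == 1]
  if (length(ref) > 0) {
    dmat <- dmat[, setdiff(colnames(dmat), ref), drop = FALSE]
  }
  fit_one <- function(series, tag) {
    y_pre <- series$value[pre_idx]
    sfit <- fit_pre_period(y_pre, order = order, seasonal = seasonal,
                           period = period,
                           xreg = dmat[pre_idx, , drop = FALSE])
    xf <- if (length(sfit$xreg_names))
      dmat[post_idx, sfit$xreg_names, drop = FALSE] else NULL
    cf <- simulate_counterfactual(sfit, horizon = k, B = B,
                                  seed = substream_seed(seed, tag),
                                  xreg_future = xf)
    single_series_z(cf, series$value[post_idx], alpha = alpha)
  }
  tr_cf <- fit_one(tr_series, "treated")
  co_cf <- fit_one(co_series, "comparator")
  comp <- comparative_z(tr_cf, co_cf, measure_kind, pooling, alpha)
  eff_tr <- effect_scale(tr_cf$diff, measure_kind)
  eff_tr_ci <- effect_scale(tr_cf$ci, measure_kind)$estimate
  list(treated = tr_cf, comparator = co_cf, comp = comp,
       effect_treated = eff_tr, effect_treated_ci = eff_tr_ci,
       n_pre = length(pre_idx), k = k)
}
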