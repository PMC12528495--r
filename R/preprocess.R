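#' Detect server-outage days in a tweet stream
#'
#' A day is an outage if and only if it contains zero user-authored
#' (non-retweet) tweets across all communities. Because an outage may have
#' begun during the preceding day or persisted into the following day --
#' leaving partial counts -- the day immediately before and immediately after
#' each outage run is dropped as well (clipped to the observed span).
#'
#' @param tweets tweet data.frame (see [read_tweet_stream()] for columns).
#' @param span optional `Date` vector `c(first, last)` fixing the observed
#'   span; defaults to the range of timestamps in the stream.
#' @param known_outages optional `Date` vector overriding detection: these
#'   days (plus flanks) are dropped regardless of observed counts, e.g. to
#'   supply an externally documented outage list.
#' @return An object of class `outage_report`: list with `outage_days`,
#'   `dropped_days` (both `Date`), `span`, and `edge_gaps` (dropped days at
#'   the span boundary, which imputation can only fill by carrying the
#'   nearest retained value).
#' @export
#' @examples
#' # a stream silent on one interior day drops that day and both neighbours
detect_outages <- function(tweets, span = NULL, known_outages = NULL) {
  if (nrow(tweets) == 0) stop_input("empty tweet stream")
  assert_columns(tweets, c("timestamp", "is_retweet"), "tweet stream")
  day <- as.Date(tweets$timestamp, tz = "UTC")
  if (is.null(span)) span <- range(day)
  all_days <- seq(span[1], span[2], by = "day")
  if (length(all_days) < 3) stop_input("stream must span at least 3 days")
  if (is.null(known_outages)) {
    authored <- unique(day[!tweets$is_retweet])
    outages <- all_days[!(all_days %in% authored)]
  } else {
    outages <- as.Date(known_outages)
    outages <- outages[outages >= span[1] & outages <= span[2]]
  }
  dropped <- sort(unique(c(outages, outages - 1, outages + 1)))
  dropped <- dropped[dropped >= span[1] & dropped <= span[2]]
  structure(
    list(outage_days = outages,
         dropped_days = dropped,
         span = span,
         edge_gaps = dropped[dropped %in% span]),
    class = "outage_report"
  )
}

#' @export
print.outage_report <- function(x, ...) {
  cat("<outage_report>", length(x$outage_days), "outage day(s),",
      length(x$dropped_days), "dropped day(s) over",
      format(x$span[1]), "..", format(x$span[2]), "\n")
  invisible(x)
}

#' Serialize an outage report to YAML
#'
#' @param report an `outage_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_outage_report <- function(report, path) {
  yaml::write_yaml(list(
    outage_days = as.character(report$outage_days),
    dropped_days = as.character(report$dropped_days),
    span = as.character(report$span),
    edge_gaps = as.character(report$edge_gaps)
  ), path)
  invisible(path)
}

#' Impute dropped days in a daily measure panel by linear interpolation
#'
#' Replaces the value on every dropped day with the linear interpolation
#' between the nearest retained neighbours, independently for each
#' (community, measure) series. Interpolation operates on whatever scale the
#' panel stores -- by convention the transformed (logit/log) scale, since
#' measures are transformed before imputation. Gaps touching the span edge
#' have no neighbour on one side and carry the nearest retained value; such
#' days are flagged in the report. Retained values are never touched, so the
#' operation is idempotent.
#'
#' @param panel daily measure data.frame with columns `community`, `date`,
#'   `measure`, `value`, `n` (as produced by the measure builders).
#' @param dropped `Date` vector of dropped days, or an `outage_report`.
#' @return The panel with dropped-day values replaced and a logical
#'   `imputed` column added.
#' @export
#' @examples
#' pan <- data.frame(community = "a", date = as.Date("2020-01-01") + 0:2,
#'                   measure = "content_logit", value = c(2, 7, 4), n = 1)
#' impute_measures(pan, as.Date("2020-01-02"))$value  # 2 3 4
impute_measures <- function(panel, dropped) {
  if (inherits(dropped, "outage_report")) dropped <- dropped$dropped_days
  dropped <- as.Date(dropped)
  assert_columns(panel, c("community", "date", "measure", "value"),
                 "measure panel")
  panel$date <- as.Date(panel$date)
  out <- panel
  out$imputed <- out$date %in% dropped | is.na(out$value)
  key <- interaction(out$community, out$measure, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    ord <- idx[order(out$date[idx])]
    v <- out$value[ord]
    v[out$imputed[ord]] <- NA_real_
    if (all(is.na(v))) {
      stop_input("all days dropped for series ", k, "; nothing to impute from")
    }
    filled <- zoo::na.approx(v, x = as.numeric(out$date[ord]), na.rm = FALSE,
                             rule = 2)
    out$value[ord] <- filled
  }
  out
}
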