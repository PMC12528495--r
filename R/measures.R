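#' Community relative-activity measure (logit content proportion)
#'
#' For each retained day, counts all tweets (including retweets and quote
#' tweets) per community, divides by the day's total across communities, and
#' applies the logit transform so the series is unbounded despite floor and
#' ceiling effects. To keep the logit defined at observed 0 or 1 proportions,
#' counts are add-one (Laplace) smoothed: `p = (count + 1) / (total + C)`
#' with `C` the number of communities; set `smoothing = FALSE` for raw
#' proportions.
#'
#' @param tweets tweet data.frame.
#' @param communities character vector fixing the community universe (and the
#'   smoothing constant); defaults to the communities present in the stream.
#' @param dropped `Date` vector (or `outage_report`) of days to emit as
#'   missing for later imputation.
#' @param smoothing add-one smoothing of counts (default `TRUE`).
#' @param period `"day"` or `"month"`; monthly values are recomputed from
#'   monthly counts, not averaged from daily values.
#' @return data.frame `community`, `date` (or `month`), `measure`
#'   (`"content_logit"`), `value`, `n` (raw tweet count).
#' @export
content_proportion <- function(tweets, communities = NULL, dropped = NULL,
                               smoothing = TRUE, period = c("day", "month")) {
  period <- match.arg(period)
  if (inherits(dropped, "outage_report")) dropped <- dropped$dropped_days
  assert_columns(tweets, c("community_id", "timestamp"), "tweet stream")
  communities <- communities %||% sort(unique(tweets$community_id))
  C <- length(communities)
  if (C < 2) stop_input("content_proportion needs >= 2 communities")
  dt <- data.table::as.data.table(tweets)
  dt <- dt[dt$community_id %in% communities, ]
  dt$date <- as.Date(dt$timestamp, tz = "UTC")
  mg <- measure_grid(dt, communities, period)
  grid <- mg$grid
  dt <- mg$dt
  counts <- dt[, list(n = .N), by = c("community_id", "bin")]
  out <- merge(grid, counts, by = c("community_id", "bin"), all.x = TRUE)
  out$n[is.na(out$n)] <- 0L
  totals <- out[, list(total = sum(n)), by = "bin"]
  out <- merge(out, totals, by = "bin")
  if (period == "day") {
    is_dropped <- out$bin %in% as.character(dropped %||% as.Date(character()))
    if (any(out$total == 0 & !is_dropped)) {
      stop_input("day(s) with zero total tweets not marked as dropped: ",
                 paste(head(unique(out$bin[out$total == 0 & !is_dropped])),
                       collapse = ", "))
    }
  } else {
    is_dropped <- rep(FALSE, nrow(out))
  }
  p <- if (smoothing) (out$n + 1) / (out$total + C) else out$n / out$total
  value <- logit(p)
  value[is_dropped | out$total == 0] <- NA_real_
  res <- data.frame(community = out$community_id,
                    date = out$bin,
                    measure = "content_logit",
                    value = value,
                    n = out$n,
                    stringsAsFactors = FALSE)
  finish_measure(res, period)
}

# bins the stream into days or months and builds the complete
# community x bin grid over the observed span
measure_grid <- function(dt, communities, period) {
  dt <- data.table::copy(dt)
  if (period == "day") {
    bins <- as.character(seq(min(dt$date), max(dt$date), by = "day"))
    dt$bin <- as.character(dt$date)
  } else {
    bins <- month_key_seq(month_key(min(dt$date)), month_key(max(dt$date)))
    dt$bin <- month_key(dt$date)
  }
  list(grid = data.table::CJ(community_id = communities, bin = bins), dt = dt)
}

finish_measure <- function(res, period) {
  if (period == "day") {
    res$date <- as.Date(res$date)
  } else {
    names(res)[names(res) == "date"] <- "month"
  }
  res[order(res$community, res[[2]]), , drop = FALSE]
}

#' Virality measure (mean log Laplace-smoothed retweets per follower)
#'
#' For each user-authored tweet, computes
#' `v = log((retweets + 1) / (followers + 1))` -- Laplace smoothing with
#' alpha = 1 keeps the ratio defined for never-retweeted tweets and accounts
#' with no followers -- and averages `v` over each community's user-authored
#' tweets per day (or month). Retweet records never enter. Community-days
#' with no user-authored tweets are emitted as missing for later imputation.
#'
#' @inheritParams content_proportion
#' @param include_quotes reserved flag for streams that distinguish quote
#'   tweets; quote records flagged `is_retweet = FALSE` count as
#'   user-authored.
#' @return data.frame `community`, `date`/`month`, `measure`
#'   (`"virality_log"`), `value`, `n` (user-authored tweets contributing).
#' @export
virality <- function(tweets, communities = NULL, dropped = NULL,
                     period = c("day", "month"), include_quotes = TRUE) {
  period <- match.arg(period)
  if (inherits(dropped, "outage_report")) dropped <- dropped$dropped_days
  assert_columns(tweets,
                 c("community_id", "timestamp", "is_retweet",
                   "retweet_count_final", "follower_count_at_post"),
                 "tweet stream")
  communities <- communities %||% sort(unique(tweets$community_id))
  dt <- data.table::as.data.table(tweets)
  dt <- dt[!dt$is_retweet & dt$community_id %in% communities, ]
  if (nrow(dt) == 0) stop_input("no user-authored tweets in stream")
  dt$date <- as.Date(dt$timestamp, tz = "UTC")
  dt$v <- log((dt$retweet_count_final + 1) / (dt$follower_count_at_post + 1))
  mg <- measure_grid(dt, communities, period)
  grid <- mg$grid
  dt <- mg$dt
  agg <- dt[, list(value = mean(v), n = .N), by = c("community_id", "bin")]
  out <- merge(grid, agg, by = c("community_id", "bin"), all.x = TRUE)
  out$n[is.na(out$n)] <- 0L
  if (!is.null(dropped) && period == "day") {
    out$value[out$bin %in% as.character(dropped)] <- NA_real_
  }
  res <- data.frame(community = out$community_id, date = out$bin,
                    measure = "virality_log", value = out$value, n = out$n,
                    stringsAsFactors = FALSE)
  finish_measure(res, period)
}

#' URL domain-quality measure (minimum rule, daily mean)
#'
#' Extracts the registered domain of every URL in every tweet (retweets and
#' quote tweets included), looks up its quality rating, scores each tweet by
#' the *minimum* rating over its rated URLs, and averages tweet scores per
#' community per day (or month). Tweets whose URLs are all unrated or
#' malformed are excluded from the denominator; malformed URLs trigger a
#' warning.
#'
#' @inheritParams content_proportion
#' @param domains domain-quality table (`domain`, `quality`), e.g. from
#'   [read_domain_table()].
#' @return data.frame `community`, `date`/`month`, `measure`
#'   (`"quality_mean"`), `value`, `n` (rated tweets contributing).
#' @export
domain_quality <- function(tweets, domains, communities = NULL,
                           dropped = NULL, period = c("day", "month")) {
  period <- match.arg(period)
  if (inherits(dropped, "outage_report")) dropped <- dropped$dropped_days
  assert_columns(tweets, c("community_id", "timestamp", "urls"),
                 "tweet stream")
  assert_columns(domains, c("domain", "quality"), "domain table")
  communities <- communities %||% sort(unique(tweets$community_id))
  lookup <- stats::setNames(domains$quality, tolower(domains$domain))
  dt <- data.table::as.data.table(tweets)
  dt <- dt[dt$community_id %in% communities, ]
  dt$date <- as.Date(dt$timestamp, tz = "UTC")
  url_lists <- strsplit(dt$urls, " ", fixed = TRUE)
  tweet_idx <- rep(seq_len(nrow(dt)), lengths(url_lists))
  us <- unlist(url_lists, use.names = FALSE)
  keep <- nzchar(us)
  us <- us[keep]
  tweet_idx <- tweet_idx[keep]
  doms <- registered_domains(us)
  n_bad <- sum(is.na(doms))
  if (n_bad > 0) warning(n_bad, " malformed URL(s) skipped")
  q <- unname(lookup[doms])
  ok <- !is.na(q)
  score <- rep(NA_real_, nrow(dt))
  if (any(ok)) {
    mins <- tapply(q[ok], tweet_idx[ok], min)
    score[as.integer(names(mins))] <- as.numeric(mins)
  }
  dt$score <- score
  mg <- measure_grid(dt, communities, period)
  grid <- mg$grid
  dt <- mg$dt
  rated <- dt[!is.na(dt$score), ]
  agg <- rated[, list(value = mean(score), n = .N),
               by = c("community_id", "bin")]
  out <- merge(grid, agg, by = c("community_id", "bin"), all.x = TRUE)
  out$n[is.na(out$n)] <- 0L
  if (!is.null(dropped) && period == "day") {
    out$value[out$bin %in% as.character(dropped)] <- NA_real_
  }
  res <- data.frame(community = out$community_id, date = out$bin,
                    measure = "quality_mean", value = out$value, n = out$n,
                    stringsAsFactors = FALSE)
  finish_measure(res, period)
}

# multi-part public suffixes recognised by the registered-domain extractor
multi_suffixes <- c(
  "co.uk", "org.uk", "ac.uk", "gov.uk", "me.uk", "net.uk",
  "com.au", "net.au", "org.au", "edu.au", "gov.au",
  "co.jp", "ne.jp", "or.jp", "ac.jp", "go.jp",
  "co.nz", "org.nz", "net.nz", "govt.nz",
  "com.br", "org.br", "net.br", "gov.br",
  "co.in", "org.in", "net.in", "gov.in", "ac.in",
  "co.za", "org.za", "net.za", "gov.za",
  "com.mx", "org.mx", "com.ar", "com.cn", "org.cn", "net.cn", "gov.cn",
  "com.sg", "com.hk", "com.tw", "co.kr", "or.kr", "go.kr",
  "com.tr", "gov.tr", "com.ua", "gov.ua"
)

#' Extract the registered domain of a URL
#'
#' Strips scheme, credentials, port, path, query, and subdomains, keeping the
#' registrable label plus its public suffix, so
#' `"www.example.com/this-is-an-example.html"` maps to `"example.com"`.
#' A compact built-in list of common multi-part suffixes (`co.uk`, `com.au`,
#' ...) is honoured.
#'
#' @param url a single URL (scheme optional).
#' @return Lower-cased registered domain, or `NA_character_` if the URL has
#'   no parseable host.
#' @export
#' @examples
#' registered_domain("www.example.com/this-is-an-example.html")  # "example.com"
#' registered_domain("https://news.bbc.co.uk/story")             # "bbc.co.uk"
registered_domain <- function(url) {
  if (length(url) != 1) stop_input("registered_domain expects one URL")
  registered_domains(url)
}

#' @rdname registered_domain
#' @param urls character vector of URLs (vectorised form).
#' @export
registered_domains <- function(urls) {
  host <- sub("^[a-zA-Z][a-zA-Z0-9+.-]*://", "", urls)
  host <- sub("^[^/@]*@", "", host)          # credentials
  host <- sub("[/?#].*$", "", host)          # path/query/fragment
  host <- sub(":[0-9]*$", "", host)          # port
  host <- tolower(host)
  host <- gsub("\\.+", ".", host)            # collapse empty labels
  host <- sub("^\\.", "", sub("\\.$", "", host))
  bad <- is.na(urls) | !nzchar(host) | grepl("[^a-z0-9.-]", host) |
    !grepl(".", host, fixed = TRUE)
  last2 <- sub("^.*?([^.]+\\.[^.]+)$", "\\1", host)
  last3 <- sub("^.*?([^.]+\\.[^.]+\\.[^.]+)$", "\\1", host)
  has3 <- grepl("\\..*\\.", host)            # at least three labels
  out <- ifelse(last2 %in% multi_suffixes & has3, last3, last2)
  out[bad] <- NA_character_
  out
}

#' Topic-category grouping rules
#'
#' The three disjoint sets of discourse categories that define the topic
#' groups, together with the number of independent raters per topic.
#' A topic is *skepticism* or *promotion* only if all raters place it in the
#' respective set; *commentary* if at least one rater places it in the
#' commentary set and no rater places it in the skepticism or promotion
#' sets; otherwise *other*.
#'
#' @return list with `skepticism`, `promotion`, `commentary`, `n_raters`.
#' @export
topic_group_rules <- function() {
  list(
    skepticism = c("Alternative medicine", "Conspiracy", "Safety concerns"),
    promotion = c("Pro-science", "Provaccine policy",
                  "Criticizing antivaccine beliefs", "Promotion",
                  "Safety and efficacy"),
    commentary = c("Civil liberties", "Morality", "Politics"),
    n_raters = 5L
  )
}

#' Aggregate per-topic rater labels into a topic group
#'
#' Applies the unanimity/veto rules of [topic_group_rules()] to the
#' `n_raters` category labels assigned to one topic.
#'
#' @param labels character vector of exactly `n_raters` (5) category labels.
#' @param rules rules list, defaults to [topic_group_rules()].
#' @return One of `"skepticism"`, `"promotion"`, `"commentary"`, `"other"`.
#' @export
#' @examples
#' aggregate_topic_labels(rep("Conspiracy", 5))            # skepticism
#' aggregate_topic_labels(c("Politics", "Morality", "Politics",
#'                          "Civil liberties", "Politics")) # commentary
aggregate_topic_labels <- function(labels, rules = topic_group_rules()) {
  if (length(labels) != rules$n_raters) {
    stop_input("expected exactly ", rules$n_raters, " rater labels, got ",
               length(labels))
  }
  in_skep <- labels %in% rules$skepticism
  in_promo <- labels %in% rules$promotion
  in_comm <- labels %in% rules$commentary
  if (all(in_skep)) return("skepticism")
  if (all(in_promo)) return("promotion")
  if (any(in_comm) && !any(in_skep) && !any(in_promo)) return("commentary")
  "other"
}

#' Map tweet topic categories to groups via simulated or supplied raters
#'
#' Builds a category-to-group map by applying [aggregate_topic_labels()] to a
#' rater-label table (one row per topic/category, `n_raters` label columns).
#' When no rater table is supplied, each category is treated as unanimously
#' rated as itself -- the degenerate rater model under which the rules reduce
#' to set membership.
#'
#' @param categories character vector of category names to map.
#' @param rater_labels optional data.frame: column `category` plus
#'   `n_raters` label columns.
#' @param rules rules list.
#' @return named character vector: category -> group.
#' @export
topic_group_map <- function(categories = topic_categories(),
                            rater_labels = NULL,
                            rules = topic_group_rules()) {
  if (is.null(rater_labels)) {
    groups <- vapply(categories, function(cat) {
      aggregate_topic_labels(rep(cat, rules$n_raters), rules)
    }, character(1))
  } else {
    assert_columns(rater_labels, "category", "rater label table")
    lab_cols <- setdiff(names(rater_labels), "category")
    if (length(lab_cols) != rules$n_raters) {
      stop_input("rater label table must have exactly ", rules$n_raters,
                 " label columns")
    }
    groups <- vapply(categories, function(cat) {
      row <- rater_labels[rater_labels$category == cat, lab_cols]
      if (nrow(row) == 0) return("other")
      aggregate_topic_labels(as.character(unlist(row[1, ])), rules)
    }, character(1))
  }
  stats::setNames(groups, categories)
}

#' Topic-group share measure (logit of smoothed share)
#'
#' Per community-day (or month), the share of each topic group among the
#' community's tweets (retweets inherit the topic of their original tweet),
#' add-one (Laplace) smoothed over the four groups --
#' `p = (count + 1) / (total + 4)` -- and logit-transformed. Unlabeled
#' tweets count in the denominator only and their number is reported.
#'
#' @inheritParams content_proportion
#' @param group_map named character vector category -> group, from
#'   [topic_group_map()].
#' @param groups which groups to emit (default all four).
#' @return data.frame `community`, `date`/`month`, `measure`
#'   (`"topic_logit_<group>"`), `value`, `n` (group tweet count). The number
#'   of unlabeled tweets is attached as attribute `n_unlabeled`.
#' @export
topic_share <- function(tweets, group_map = topic_group_map(),
                        communities = NULL, dropped = NULL,
                        smoothing = TRUE, period = c("day", "month"),
                        groups = c("skepticism", "promotion", "commentary",
                                   "other")) {
  period <- match.arg(period)
  if (inherits(dropped, "outage_report")) dropped <- dropped$dropped_days
  assert_columns(tweets, c("community_id", "timestamp", "topic_label"),
                 "tweet stream")
  communities <- communities %||% sort(unique(tweets$community_id))
  n_groups <- 4L  # smoothing constant: the closed set of groups
  dt <- data.table::as.data.table(tweets)
  dt <- dt[dt$community_id %in% communities, ]
  dt$date <- as.Date(dt$timestamp, tz = "UTC")
  dt$group <- unname(group_map[dt$topic_label])
  n_unlabeled <- sum(is.na(dt$group))
  mg <- measure_grid(dt, communities, period)
  grid <- mg$grid
  dt <- mg$dt
  totals <- dt[, list(total = .N), by = c("community_id", "bin")]
  res_list <- lapply(groups, function(g) {
    cnt <- dt[!is.na(dt$group) & dt$group == g,
              list(n = .N), by = c("community_id", "bin")]
    out <- merge(grid, cnt, by = c("community_id", "bin"), all.x = TRUE)
    out$n[is.na(out$n)] <- 0L
    out <- merge(out, totals, by = c("community_id", "bin"), all.x = TRUE)
    out$total[is.na(out$total)] <- 0L
    p <- if (smoothing) (out$n + 1) / (out$total + n_groups)
         else out$n / out$total
    value <- logit(p)
    value[out$total == 0] <- NA_real_
    if (!is.null(dropped) && period == "day") {
      value[out$bin %in% as.character(dropped)] <- NA_real_
    }
    data.frame(community = out$community_id, date = out$bin,
               measure = paste0("topic_logit_", g), value = value, n = out$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res_list)
  res <- finish_measure(res, period)
  attr(res, "n_unlabeled") <- n_unlabeled
  res
}

#' Build all daily (or monthly) measures for a stream
#'
#' Convenience wrapper running [content_proportion()], [virality()],
#' [domain_quality()], and optionally [topic_share()] and stacking the
#' results into one tidy panel.
#'
#' @inheritParams content_proportion
#' @param domains domain-quality table; quality measure skipped if `NULL`.
#' @param group_map category -> group map; topic measures skipped if `NULL`.
#' @return tidy data.frame `community`, `date`/`month`, `measure`, `value`,
#'   `n`.
#' @export
build_measures <- function(tweets, domains = NULL,
                           group_map = topic_group_map(),
                           communities = NULL, dropped = NULL,
                           period = c("day", "month")) {
  period <- match.arg(period)
  parts <- list(
    content_proportion(tweets, communities, dropped, period = period),
    virality(tweets, communities, dropped, period = period)
  )
  if (!is.null(domains)) {
    parts <- c(parts, list(
      domain_quality(tweets, domains, communities, dropped, period = period)))
  }
  if (!is.null(group_map) && !all(is.na(tweets$topic_label))) {
    parts <- c(parts, list(
      topic_share(tweets, group_map, communities, dropped, period = period)))
  }
  do.call(rbind, parts)
}

#' Aggregate a tweet stream to calendar-month measures
#'
#' Monthly values are recomputed from raw tweet-level data -- proportions
#' from monthly counts then logit; virality and quality averaged over the
#' month's tweet-level values -- not averaged from daily series. Partial
#' first/last months are included and flagged.
#'
#' @inheritParams build_measures
#' @return tidy monthly data.frame with a logical `partial_month` attribute
#'   naming months not fully covered by the stream's span.
#' @export
monthly_aggregate <- function(tweets, domains = NULL,
                              group_map = topic_group_map(),
                              communities = NULL) {
  res <- build_measures(tweets, domains, group_map, communities,
                        period = "month")
  day <- as.Date(tweets$timestamp, tz = "UTC")
  span <- range(day)
  mk <- sort(unique(res$month))
  partial <- vapply(mk, function(m) {
    first <- as.Date(paste0(m, "-01"))
    last <- seq(first, by = "month", length.out = 2)[2] - 1
    first < span[1] || last > span[2]
  }, logical(1))
  attr(res, "partial_months") <- mk[partial]
  res
}
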