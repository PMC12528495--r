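test_that("content proportions are symmetric, normalised, and logit-scaled", {
  counts <- list(community_01 = rep(50, 3), community_02 = rep(50, 3))
  m <- content_proportion(counted_stream(counts))
  expect_true(all(abs(m$value) < 1e-12))

  counts2 <- list(community_01 = rep(75, 3), community_02 = rep(25, 3))
  m2 <- content_proportion(counted_stream(counts2), smoothing = FALSE)
  expect_equal(unique(round(m2$value[m2$community == "community_01"], 6)),
               round(log(3), 6))

  # pre-transform proportions sum to 1 on every day, with and without smoothing
  for (sm in c(TRUE, FALSE)) {
    m3 <- content_proportion(counted_stream(list(
      community_01 = c(5, 9, 1), community_02 = c(2, 2, 8),
      community_03 = c(1, 4, 4))), smoothing = sm)
    sums <- as.numeric(tapply(inv_logit(m3$value), m3$date, sum))
    expect_equal(sums, rep(1, 3), tolerance = 1e-12)
  }
})

test_that("content proportion counts retweets and quote records too", {
  stream <- rbind(
    counted_stream(list(community_01 = rep(2, 3), community_02 = rep(2, 3))),
    tweet_row("rt1", community = "community_01", day = as.Date("2020-03-01"),
              is_retweet = TRUE, retweeted_id = "community_01_d001_0001"))
  m <- content_proportion(stream, smoothing = FALSE)
  d1 <- m[m$date == as.Date("2020-03-01") & m$community == "community_01", ]
  expect_equal(d1$n, 3L)
  expect_equal(d1$value, log(3 / 2))
})

test_that("a zero-total day must have been dropped upstream", {
  counts <- list(community_01 = c(3, 0, 3), community_02 = c(3, 0, 3))
  stream <- counted_stream(counts)
  expect_error(content_proportion(stream), "not marked as dropped")
  m <- content_proportion(stream, dropped = as.Date("2020-03-02"))
  expect_true(all(is.na(m$value[m$date == as.Date("2020-03-02")])))
})

test_that("virality applies the Laplace-smoothed log ratio and averages per day", {
  stream <- rbind(
    tweet_row("t1", followers = 0L, retweets = 0L),
    tweet_row("t2", followers = 999L, retweets = 499L, secs = 1),
    tweet_row("t3", community = "community_02", followers = 9L,
              retweets = 4L))
  m <- virality(stream)
  v1 <- m$value[m$community == "community_01"]
  # tweet scores: log(1/1) = 0 and log(500/1000); the day averages them
  expect_equal(v1, (0 + log(0.5)) / 2)
  expect_equal(m$value[m$community == "community_02"], log(5 / 10))
})

test_that("virality ignores retweet records and flags silent community-days", {
  stream <- rbind(
    counted_stream(list(community_01 = c(2, 2), community_02 = c(2, 0))),
    tweet_row("rt", community = "community_02", day = as.Date("2020-03-02"),
              is_retweet = TRUE, retweeted_id = "x", followers = 10L,
              retweets = 999L))
  m <- virality(stream)
  gap <- m[m$community == "community_02" & m$date == as.Date("2020-03-02"), ]
  expect_true(is.na(gap$value))
  expect_equal(gap$n, 0L)
})

test_that("registered domains follow the public-suffix rule", {
  expect_equal(registered_domain("www.example.com/this-is-an-example.html"),
               "example.com")
  expect_equal(registered_domain("https://news.bbc.co.uk/story?id=1"),
               "bbc.co.uk")
  expect_equal(registered_domain("http://sub.a.example.org:8080/x"),
               "example.org")
  expect_equal(registered_domain("example.com"), "example.com")
  expect_true(is.na(registered_domain("not a url")))
  expect_true(is.na(registered_domain("")))
})

quality_fixture <- function() {
  data.frame(domain = c("good.org", "bad.net", "mid.com"),
             quality = c(0.9, 0.2, 0.5), stringsAsFactors = FALSE)
}

test_that("tweet quality takes the minimum over rated URLs", {
  tab <- quality_fixture()
  stream <- rbind(
    tweet_row("t1", urls = "https://www.good.org/a http://bad.net/b"),
    tweet_row("t2", urls = "https://www.good.org/a", secs = 1))
  m <- domain_quality(stream, tab)
  expect_equal(m$value, (0.2 + 0.9) / 2)

  # a single shared domain pins the daily mean at its rating
  one <- domain_quality(rbind(
    tweet_row("a", urls = "mid.com/x"),
    tweet_row("b", urls = "www.mid.com/y", secs = 1)), tab)
  expect_equal(one$value, 0.5)
})

test_that("unrated and malformed URLs drop out of the quality denominator", {
  tab <- quality_fixture()
  stream <- rbind(
    tweet_row("t1", urls = "unknown-domain.io/z"),
    tweet_row("t2", urls = "good.org/a", secs = 1),
    tweet_row("t3", urls = "http://%%%bad host%%%", secs = 2),
    tweet_row("t4", secs = 3))
  expect_warning(m <- domain_quality(stream, tab), "malformed")
  expect_equal(m$value, 0.9)
  expect_equal(m$n, 1L)
})

test_that("lowering any URL rating never raises a day's quality", {
  tab <- quality_fixture()
  stream <- rbind(
    tweet_row("t1", urls = "good.org/a mid.com/b"),
    tweet_row("t2", urls = "mid.com/c", secs = 1),
    tweet_row("t3", urls = "bad.net/d good.org/e", secs = 2))
  base <- domain_quality(stream, tab)$value
  for (i in seq_len(nrow(tab))) {
    lowered <- tab
    lowered$quality[i] <- max(lowered$quality[i] - 0.3, 0)
    expect_lte(domain_quality(stream, lowered)$value, base + 1e-12)
  }
})

test_that("topic label aggregation follows the unanimity and veto rules", {
  expect_equal(aggregate_topic_labels(rep("Conspiracy", 5)), "skepticism")
  expect_equal(aggregate_topic_labels(c("Alternative medicine", "Conspiracy",
                                        "Safety concerns", "Conspiracy",
                                        "Safety concerns")), "skepticism")
  expect_equal(aggregate_topic_labels(rep("Promotion", 5)), "promotion")
  expect_equal(aggregate_topic_labels(c("Politics", "Morality", "Politics",
                                        "Civil liberties", "Politics")),
               "commentary")
  expect_equal(aggregate_topic_labels(c("Politics", "Anecdotes", "Politics",
                                        "Politics", "Politics")),
               "commentary")
  expect_equal(aggregate_topic_labels(c(rep("Conspiracy", 4), "Promotion")),
               "other")
  expect_equal(aggregate_topic_labels(c("Politics", "Conspiracy", "Politics",
                                        "Politics", "Politics")), "other")
  expect_equal(aggregate_topic_labels(rep("Anecdotes", 5)), "other")
  expect_error(aggregate_topic_labels(rep("Conspiracy", 4)), "exactly 5")
})

# independent oracle: literal transcription of the grouping rules
naive_topic_group <- function(labels) {
  skep <- c("Alternative medicine", "Conspiracy", "Safety concerns")
  promo <- c("Pro-science", "Provaccine policy",
             "Criticizing antivaccine beliefs", "Promotion",
             "Safety and efficacy")
  comm <- c("Civil liberties", "Morality", "Politics")
  if (sum(labels %in% skep) == 5) return("skepticism")
  if (sum(labels %in% promo) == 5) return("promotion")
  if (sum(labels %in% comm) >= 1 &&
      sum(labels %in% c(skep, promo)) == 0) return("commentary")
  "other"
}

test_that("aggregation agrees with brute-force rule enumeration on random tuples", {
  cats <- setdiff(topic_categories(), "Other")
  set.seed(42)
  for (i in 1:2000) {
    labels <- sample(cats, 5, replace = TRUE)
    expect_identical(aggregate_topic_labels(labels),
                     naive_topic_group(labels))
  }
})

test_that("topic shares are Laplace-smoothed over the four groups", {
  day <- as.Date("2020-03-01")
  rows <- c(lapply(1:3, function(i) {
    tweet_row(paste0("s", i), secs = i, topic = "Conspiracy")
  }), lapply(1:7, function(i) {
    tweet_row(paste0("p", i), secs = 10 + i, topic = "Promotion")
  }))
  stream <- do.call(rbind, rows)
  m <- topic_share(stream)
  skep <- m[m$measure == "topic_logit_skepticism", ]
  expect_equal(inv_logit(skep$value), (3 + 1) / (10 + 4))
  shares <- tapply(inv_logit(m$value), m$measure, sum)
  expect_equal(sum(shares), 1, tolerance = 1e-12)
})

test_that("unlabeled tweets stay in the topic-share denominator only", {
  stream <- rbind(tweet_row("a", topic = "Conspiracy"),
                  tweet_row("b", secs = 1),
                  tweet_row("c", secs = 2, topic = "Promotion"))
  m <- topic_share(stream, smoothing = FALSE)
  expect_equal(attr(m, "n_unlabeled"), 1L)
  skep <- m[m$measure == "topic_logit_skepticism", ]
  expect_equal(inv_logit(skep$value), 1 / 3)
})

test_that("monthly aggregation recomputes from raw counts", {
  start <- as.Date("2020-03-01")
  counts <- list(community_01 = rep(10, 40), community_02 = rep(10, 40))
  counts$community_01[1:31] <- 30   # March: 930 vs 310
  stream <- counted_stream(counts, start)
  m <- content_proportion(stream, period = "month", smoothing = FALSE)
  mar <- m[m$month == "2020-03" & m$community == "community_01", ]
  expect_equal(inv_logit(mar$value), 0.75)
  # conservation: monthly counts equal summed daily counts
  daily <- content_proportion(stream)
  expect_equal(sum(m$n), sum(daily$n))
  expect_equal(sum(m$n), nrow(stream))
})

test_that("a constant daily series aggregates to the same monthly value", {
  stream <- rbind(
    do.call(rbind, lapply(1:35, function(d) {
      tweet_row(paste0("x", d), day = as.Date("2020-03-01") + d - 1,
                followers = 99L, retweets = 49L)
    })),
    do.call(rbind, lapply(1:35, function(d) {
      tweet_row(paste0("y", d), community = "community_02",
                day = as.Date("2020-03-01") + d - 1,
                followers = 9L, retweets = 9L)
    })))
  m <- virality(stream, period = "month")
  expect_equal(m$value[m$community == "community_01"], rep(log(0.5), 2))
  mon <- monthly_aggregate(stream, domains = quality_fixture())
  expect_true(all(c("2020-03", "2020-04") %in% mon$month))
  expect_equal(attr(mon, "partial_months"), "2020-04")
})

test_that("topic group map handles rater tables and degenerate raters", {
  gm <- topic_group_map()
  expect_equal(unname(gm["Conspiracy"]), "skepticism")
  expect_equal(unname(gm["Promotion"]), "promotion")
  expect_equal(unname(gm["Politics"]), "commentary")
  expect_equal(unname(gm["Anecdotes"]), "other")

  raters <- data.frame(category = c("TopicA", "TopicB"),
                       r1 = c("Conspiracy", "Politics"),
                       r2 = c("Conspiracy", "Morality"),
                       r3 = c("Safety concerns", "Politics"),
                       r4 = c("Conspiracy", "Anecdotes"),
                       r5 = c("Conspiracy", "Politics"),
                       stringsAsFactors = FALSE)
  gm2 <- topic_group_map(c("TopicA", "TopicB"), raters)
  expect_equal(unname(gm2), c("skepticism", "commentary"))
  bad <- raters[, 1:4]
  expect_error(topic_group_map("TopicA", bad), "exactly 5")
})
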