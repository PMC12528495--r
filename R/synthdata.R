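#' Vaccine-discourse topic categories
#'
#' The twelve discourse categories used for topic labelling, plus the residual
#' "Other" bucket. Three of them mark vaccine skepticism, five mark vaccine
#' promotion and three mark civil-liberties/moral/political commentary; see
#' [topic_group_rules()].
#'
#' @return Character vector of 13 category names.
#' @export
topic_categories <- function() {
  c("Alternative medicine", "Conspiracy", "Safety concerns",
    "Pro-science", "Provaccine policy", "Criticizing antivaccine beliefs",
    "Promotion", "Safety and efficacy",
    "Civil liberties", "Morality", "Politics",
    "Anecdotes", "Other")
}

#' Default synthetic domain pool
#'
#' A small pool of fictitious news/health domains with quality ratings spread
#' over \[0, 1\], standing in for an external expert-consensus domain-quality
#' list. All domains are clearly synthetic.
#'
#' @return data.frame with columns `domain`, `quality`.
#' @export
default_domain_pool <- function() {
  data.frame(
    domain  = c("health-agency-example.org", "university-example.edu",
                "public-news-example.com", "regional-daily-example.com",
                "wellness-blog-example.net", "alt-health-example.com",
                "conspiracy-wire-example.com", "rumor-mill-example.net",
                "fact-check-example.org", "science-desk-example.com",
                "tabloid-example.com", "fringe-forum-example.net"),
    quality = c(0.95, 0.92, 0.85, 0.72, 0.45, 0.30,
                0.10, 0.05, 0.90, 0.88, 0.35, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Specify a known ground-truth intervention
#'
#' Describes a step intervention injected into the synthetic ecosystem at a
#' known date, with known effect sizes: a multiplicative factor on daily
#' tweet volume (an odds-scale ground truth for relative-activity analyses,
#' since multiplying one community's volume multiplies its odds of authoring
#' a given tweet), a multiplicative factor on the per-follower retweet rate
#' (a rate-scale ground truth), an additive shift on mean URL domain quality,
#' and per-category log-odds shifts on the topic mixture.
#'
#' @param communities character vector of target community ids.
#' @param start_date `Date`; first day the intervention is active (inclusive).
#' @param effect_on_volume multiplicative factor > 0 on daily volume.
#' @param effect_on_virality multiplicative factor > 0 on the retweet rate.
#' @param effect_on_quality additive shift on the expected domain quality.
#' @param effect_on_topic_shares optional named numeric vector of log-odds
#'   shifts, names from [topic_categories()].
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(communities, start_date,
                              effect_on_volume = 1,
                              effect_on_virality = 1,
                              effect_on_quality = 0,
                              effect_on_topic_shares = NULL) {
  if (effect_on_volume <= 0 || effect_on_virality <= 0) {
    stop_input("intervention effect factors must be > 0 ",
               "(effect_on_volume, effect_on_virality)")
  }
  if (!is.null(effect_on_topic_shares)) {
    bad <- setdiff(names(effect_on_topic_shares), topic_categories())
    if (length(bad) > 0) {
      stop_input("effect_on_topic_shares names unknown categories: ",
                 paste(bad, collapse = ", "))
    }
  }
  structure(
    list(communities = as.character(communities),
         start_date = as.Date(start_date),
         effect_on_volume = effect_on_volume,
         effect_on_virality = effect_on_virality,
         effect_on_quality = effect_on_quality,
         effect_on_topic_shares = effect_on_topic_shares),
    class = "intervention_spec"
  )
}

default_topic_mixture <- function(n_communities) {
  cats <- topic_categories()
  skeptic <- c("Alternative medicine" = 0.12, "Conspiracy" = 0.12,
               "Safety concerns" = 0.12, "Pro-science" = 0.04,
               "Provaccine policy" = 0.03,
               "Criticizing antivaccine beliefs" = 0.03, "Promotion" = 0.03,
               "Safety and efficacy" = 0.03, "Civil liberties" = 0.12,
               "Morality" = 0.08, "Politics" = 0.12, "Anecdotes" = 0.08,
               "Other" = 0.08)
  promo <- c("Alternative medicine" = 0.03, "Conspiracy" = 0.02,
             "Safety concerns" = 0.05, "Pro-science" = 0.14,
             "Provaccine policy" = 0.10,
             "Criticizing antivaccine beliefs" = 0.10, "Promotion" = 0.14,
             "Safety and efficacy" = 0.12, "Civil liberties" = 0.05,
             "Morality" = 0.04, "Politics" = 0.05, "Anecdotes" = 0.08,
             "Other" = 0.08)
  mix <- matrix(NA_real_, n_communities, length(cats),
                dimnames = list(NULL, cats))
  for (i in seq_len(n_communities)) {
    mix[i, ] <- if (i <= ceiling(n_communities / 2)) skeptic[cats] else promo[cats]
  }
  mix / rowSums(mix)
}

community_ids <- function(n) sprintf("community_%02d", seq_len(n))

#' Configure the synthetic tweet ecosystem
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' the study conditions the pipeline is designed for: 25 communities with
#' heterogeneous baseline volumes, observed from 2020-02-07 for 1045 days,
#' log-linear AR(1) daily volumes with a shared weekly sinusoid, heavy-tailed
#' (log-normal) follower counts, Poisson (optionally negative-binomial)
#' retweet counts driven by an autocorrelated per-follower retweet rate, URL
#' sharing from a quality-rated domain pool with community-specific quality
#' tilts, topic-category mixtures, and injectable step interventions.
#'
#' @param n_communities number of communities.
#' @param days number of simulated days.
#' @param start_date first simulated day.
#' @param baseline_volume numeric vector (recycled) of expected user-authored
#'   tweets/day per community; default log-spaced from 500 down to 50.
#' @param ar_coefficient AR(1) coefficient of log daily volume, in (-1, 1).
#' @param ar_sd innovation SD of log daily volume.
#' @param weekly_seasonality_amplitude amplitude of the weekly sinusoid on
#'   the log-volume scale (0 disables it).
#' @param follower_meanlog,follower_sdlog log-normal parameters of follower
#'   counts at posting.
#' @param retweet_rate expected retweets per follower for a user-authored tweet.
#' @param retweet_dispersion negative-binomial size for retweet counts;
#'   `Inf` (default) gives Poisson counts.
#' @param virality_ar,virality_sd AR(1) coefficient and innovation SD of the
#'   day-level log retweet-rate fluctuation (news-cycle noise).
#' @param url_probability probability a user-authored tweet carries a URL.
#' @param domain_pool data.frame `domain`, `quality` (ratings in \[0, 1\]).
#' @param quality_tilt numeric vector (recycled): community-level exponential
#'   tilt on domain quality (positive prefers high-quality domains); default
#'   spreads from -1.5 to 1.5 so communities differ in baseline quality.
#' @param topic_mixture matrix `n_communities x 13` of topic-category
#'   probabilities (rows sum to 1, columns named as [topic_categories()]).
#' @param retweet_stream_rate expected retweet records per user-authored tweet.
#' @param accounts_per_community account pool size per community.
#' @param within_community_prob probability a retweet stays inside its
#'   community.
#' @param interventions list of [intervention_spec()] objects.
#' @param outage_days `Date` vector of server-outage days (no records at all).
#' @param seed root integer seed; all substreams derive from it via
#'   [substream_seed()].
#' @return An object of class `ecosystem_config`.
#' @export
ecosystem_config <- function(n_communities = 25,
                             days = 1045,
                             start_date = as.Date("2020-02-07"),
                             baseline_volume = NULL,
                             ar_coefficient = 0.6,
                             ar_sd = 0.15,
                             weekly_seasonality_amplitude = 0.15,
                             follower_meanlog = 7.5,
                             follower_sdlog = 1.0,
                             retweet_rate = 0.02,
                             retweet_dispersion = Inf,
                             virality_ar = 0.5,
                             virality_sd = 0.1,
                             url_probability = 0.35,
                             domain_pool = default_domain_pool(),
                             quality_tilt = NULL,
                             topic_mixture = NULL,
                             retweet_stream_rate = 0.5,
                             accounts_per_community = 50,
                             within_community_prob = 0.9,
                             interventions = list(),
                             outage_days = as.Date(character()),
                             seed = 1L) {
  if (is.null(baseline_volume)) {
    baseline_volume <- round(exp(seq(log(500), log(50),
                                     length.out = max(n_communities, 2))))[
                                       seq_len(n_communities)]
  }
  baseline_volume <- rep_len(baseline_volume, n_communities)
  if (is.null(quality_tilt)) {
    quality_tilt <- seq(-1.5, 1.5, length.out = max(n_communities, 2))[
      seq_len(n_communities)]
  }
  quality_tilt <- rep_len(quality_tilt, n_communities)
  if (is.null(topic_mixture)) topic_mixture <- default_topic_mixture(n_communities)
  if (inherits(interventions, "intervention_spec")) {
    interventions <- list(interventions)
  }
  cfg <- structure(
    list(n_communities = as.integer(n_communities),
         days = as.integer(days),
         start_date = as.Date(start_date),
         baseline_volume = baseline_volume,
         ar_coefficient = ar_coefficient,
         ar_sd = ar_sd,
         weekly_seasonality_amplitude = weekly_seasonality_amplitude,
         follower_meanlog = follower_meanlog,
         follower_sdlog = follower_sdlog,
         retweet_rate = retweet_rate,
         retweet_dispersion = retweet_dispersion,
         virality_ar = virality_ar,
         virality_sd = virality_sd,
         url_probability = url_probability,
         domain_pool = domain_pool,
         quality_tilt = quality_tilt,
         topic_mixture = topic_mixture,
         retweet_stream_rate = retweet_stream_rate,
         accounts_per_community = as.integer(accounts_per_community),
         within_community_prob = within_community_prob,
         interventions = interventions,
         outage_days = as.Date(outage_days),
         seed = as.integer(seed)),
    class = "ecosystem_config"
  )
  validate_ecosystem_config(cfg)
  cfg
}

# Exponential tilt over the domain pool: weights proportional to exp(eta * q).
tilted_domain_weights <- function(quality, eta) {
  w <- exp(eta * (quality - mean(quality)))
  w / sum(w)
}

tilted_mean_quality <- function(quality, eta) {
  sum(tilted_domain_weights(quality, eta) * quality)
}

# Solve for the tilt that achieves a target mean quality.
solve_quality_tilt <- function(quality, target) {
  if (target <= min(quality) || target >= max(quality)) {
    stop_input("effect_on_quality: target mean quality ", round(target, 3),
               " is outside the achievable range (",
               round(min(quality), 3), ", ", round(max(quality), 3),
               ") of the domain pool")
  }
  uniroot(function(eta) tilted_mean_quality(quality, eta) - target,
          interval = c(-80, 80), tol = 1e-10)$root
}

validate_ecosystem_config <- function(cfg) {
  span_end <- cfg$start_date + cfg$days - 1L
  if (cfg$n_communities < 1) stop_input("n_communities must be >= 1")
  if (cfg$days < 1) stop_input("days must be >= 1")
  if (any(cfg$baseline_volume <= 0)) {
    stop_input("baseline_volume: all volumes must be > 0")
  }
  if (abs(cfg$ar_coefficient) >= 1) {
    stop_input("ar_coefficient must lie in (-1, 1)")
  }
  if (cfg$weekly_seasonality_amplitude < 0) {
    stop_input("weekly_seasonality_amplitude must be >= 0")
  }
  if (any(cfg$domain_pool$quality < 0 | cfg$domain_pool$quality > 1)) {
    stop_input("domain_pool: quality ratings must lie in [0, 1]")
  }
  if (anyDuplicated(tolower(cfg$domain_pool$domain))) {
    stop_input("domain_pool: domains must be unique")
  }
  mix <- cfg$topic_mixture
  if (!is.matrix(mix) || nrow(mix) != cfg$n_communities ||
      ncol(mix) != length(topic_categories())) {
    stop_input("topic_mixture must be an n_communities x ",
               length(topic_categories()), " matrix")
  }
  if (any(abs(rowSums(mix) - 1) > 1e-9) || any(mix < 0)) {
    stop_input("topic_mixture rows must be non-negative and sum to 1")
  }
  ids <- community_ids(cfg$n_communities)
  for (iv in cfg$interventions) {
    if (!inherits(iv, "intervention_spec")) {
      stop_input("interventions must be intervention_spec objects")
    }
    bad <- setdiff(iv$communities, ids)
    if (length(bad) > 0) {
      stop_input("interventions: unknown community id(s): ",
                 paste(bad, collapse = ", "))
    }
    if (iv$start_date <= cfg$start_date || iv$start_date > span_end) {
      stop_input("interventions: start_date ", format(iv$start_date),
                 " outside the simulated span")
    }
    if (iv$effect_on_quality != 0) {
      idx <- match(iv$communities, ids)
      for (i in idx) {
        base_mean <- tilted_mean_quality(cfg$domain_pool$quality,
                                         cfg$quality_tilt[i])
        # errors if unachievable
        solve_quality_tilt(cfg$domain_pool$quality,
                           base_mean + iv$effect_on_quality)
      }
    }
  }
  if (length(cfg$outage_days) > 0 &&
      (any(cfg$outage_days < cfg$start_date) ||
       any(cfg$outage_days > span_end))) {
    stop_input("outage_days: dates outside the simulated span")
  }
  invisible(cfg)
}

# Per-community daily multipliers/shifts implied by the intervention list.
intervention_schedule <- function(cfg) {
  ids <- community_ids(cfg$n_communities)
  dates <- seq(cfg$start_date, by = "day", length.out = cfg$days)
  vol <- matrix(1, cfg$n_communities, cfg$days, dimnames = list(ids, NULL))
  vir <- matrix(1, cfg$n_communities, cfg$days, dimnames = list(ids, NULL))
  qual <- matrix(0, cfg$n_communities, cfg$days, dimnames = list(ids, NULL))
  topic <- vector("list", cfg$n_communities)
  names(topic) <- ids
  for (iv in cfg$interventions) {
    active <- dates >= iv$start_date
    for (cid in iv$communities) {
      vol[cid, active] <- vol[cid, active] * iv$effect_on_volume
      vir[cid, active] <- vir[cid, active] * iv$effect_on_virality
      qual[cid, active] <- qual[cid, active] + iv$effect_on_quality
      if (!is.null(iv$effect_on_topic_shares)) {
        topic[[cid]] <- c(topic[[cid]],
                          list(list(start = iv$start_date,
                                    shifts = iv$effect_on_topic_shares)))
      }
    }
  }
  list(volume = vol, virality = vir, quality = qual, topic = topic,
       dates = dates)
}

shifted_mixture <- function(mix_row, shifts_list, date) {
  p <- mix_row
  for (sh in shifts_list) {
    if (date >= sh$start) {
      s <- rep(0, length(p))
      names(s) <- names(p)
      s[names(sh$shifts)] <- sh$shifts
      p <- p * exp(s)
      p <- p / sum(p)
    }
  }
  p
}

#' Generate a synthetic tweet ecosystem with known ground truth
#'
#' Simulates the full synthetic ecosystem: a tweet stream (user-authored
#' tweets plus retweet records), an aggregated retweet edge list, the domain
#' quality table, a monthly transparency table of moderation counts, and a
#' ground-truth ledger recording every injected intervention effect.
#'
#' Daily user-authored volume for community *c* follows
#' `exp(log(baseline_c) + AR(1) + weekly sinusoid)`, multiplied by the active
#' interventions' volume factors, with Poisson day counts. Each tweet draws a
#' log-normal follower count, a Poisson (or negative-binomial) retweet count
#' with mean `retweet_rate x followers` times the day's autocorrelated rate
#' fluctuation and any active virality factor, a URL from the quality-tilted
#' domain pool (tilt re-solved so active quality interventions shift the mean
#' by exactly their additive effect), and a topic label from the (possibly
#' shifted) category mixture. Outage days contain no records. Everything is
#' reproducible from `config$seed`, with per-community and per-community-day
#' substreams so partial regeneration is stable.
#'
#' @param config an [ecosystem_config()].
#' @return An object of class `ecosystem`: a list with elements `tweets`,
#'   `edges`, `domains`, `transparency`, `ledger`, `config`.
#' @export
#' @examples
#' cfg <- ecosystem_config(n_communities = 2, days = 30, baseline_volume = 20,
#'                         accounts_per_community = 10)
#' eco <- generate_ecosystem(cfg)
#' head(eco$tweets)
generate_ecosystem <- function(config) {
  validate_ecosystem_config(config)
  cfg <- config
  ids <- community_ids(cfg$n_communities)
  sched <- intervention_schedule(cfg)
  dates <- sched$dates
  is_outage <- dates %in% cfg$outage_days
  nq <- cfg$domain_pool$quality
  ndom <- nrow(cfg$domain_pool)
  cats <- topic_categories()

  # community-level latent paths: AR(1) log-volume and AR(1) log-rate noise
  week_sin <- cfg$weekly_seasonality_amplitude *
    sin(2 * pi * (seq_len(cfg$days) - 1) / 7)
  latent <- lapply(seq_len(cfg$n_communities), function(ci) {
    with_seed(substream_seed(cfg$seed, "latent", ids[ci]), {
      phi <- cfg$ar_coefficient
      s <- numeric(cfg$days)
      s[1] <- rnorm(1, 0, cfg$ar_sd / sqrt(1 - phi^2))
      innov <- rnorm(cfg$days - 1, 0, cfg$ar_sd)
      for (t in seq_len(cfg$days - 1)) s[t + 1] <- phi * s[t] + innov[t]
      phv <- cfg$virality_ar
      u <- numeric(cfg$days)
      u[1] <- rnorm(1, 0, cfg$virality_sd / sqrt(1 - phv^2))
      innov_u <- rnorm(cfg$days - 1, 0, cfg$virality_sd)
      for (t in seq_len(cfg$days - 1)) u[t + 1] <- phv * u[t] + innov_u[t]
      list(volume = s, virality = u)
    })
  })

  # per-community domain weights: baseline and (lazily solved) shifted tilts
  base_mean_q <- vapply(cfg$quality_tilt, function(e) tilted_mean_quality(nq, e),
                        numeric(1))
  tilt_cache <- new.env(parent = emptyenv())
  weights_for <- function(ci, qshift) {
    if (qshift == 0) return(tilted_domain_weights(nq, cfg$quality_tilt[ci]))
    key <- paste0(ci, "_", signif(qshift, 10))
    if (is.null(tilt_cache[[key]])) {
      eta <- solve_quality_tilt(nq, base_mean_q[ci] + qshift)
      tilt_cache[[key]] <- tilted_domain_weights(nq, eta)
    }
    tilt_cache[[key]]
  }

  account_pool <- lapply(seq_len(cfg$n_communities), function(ci) {
    sprintf("user_%02d_%04d", ci, seq_len(cfg$accounts_per_community))
  })
  zipf_w <- 1 / seq_len(cfg$accounts_per_community)

  day_tables <- vector("list", cfg$n_communities * cfg$days)
  slot <- 0L
  for (ci in seq_len(cfg$n_communities)) {
    cid <- ids[ci]
    topic_shifts <- sched$topic[[cid]]
    for (d in seq_len(cfg$days)) {
      if (is_outage[d]) next
      slot <- slot + 1L
      day_tables[[slot]] <- with_seed(
        substream_seed(cfg$seed, "tweets", cid, d), {
          lambda <- cfg$baseline_volume[ci] *
            exp(latent[[ci]]$volume[d] + week_sin[d]) *
            sched$volume[ci, d]
          n <- rpois(1, lambda)
          if (n == 0) return(NULL)
          followers <- pmax(0L, as.integer(round(
            rlnorm(n, cfg$follower_meanlog, cfg$follower_sdlog))))
          rate <- cfg$retweet_rate * exp(latent[[ci]]$virality[d]) *
            sched$virality[ci, d]
          mu <- rate * followers
          rts <- if (is.finite(cfg$retweet_dispersion)) {
            rnbinom(n, size = cfg$retweet_dispersion, mu = mu)
          } else {
            rpois(n, mu)
          }
          has_url <- runif(n) < cfg$url_probability
          urls <- character(n)
          if (any(has_url)) {
            w <- weights_for(ci, sched$quality[ci, d])
            dom <- sample.int(ndom, sum(has_url), replace = TRUE, prob = w)
            urls[has_url] <- paste0("https://www.",
                                    cfg$domain_pool$domain[dom], "/post")
          }
          mix <- shifted_mixture(cfg$topic_mixture[ci, ], topic_shifts,
                                 dates[d])
          topics <- cats[sample.int(length(cats), n, replace = TRUE,
                                    prob = mix)]
          authors <- account_pool[[ci]][
            sample.int(cfg$accounts_per_community, n, replace = TRUE,
                       prob = zipf_w)]
          secs <- sort(as.integer(floor(runif(n, 0, 86400))))
          tw <- list(
            tweet_id = sprintf("t_%02d_%04d_%05d", ci, d, seq_len(n)),
            author_id = authors,
            community_id = rep(cid, n),
            timestamp = as.POSIXct(dates[d], tz = "UTC") + secs,
            is_retweet = rep(FALSE, n),
            retweeted_id = rep(NA_character_, n),
            follower_count_at_post = followers,
            retweet_count_final = as.integer(rts),
            urls = urls,
            topic_label = topics
          )
          # retweet records of today's user tweets, weighted by retweet counts
          n_rt <- rpois(1, cfg$retweet_stream_rate * n)
          if (n_rt > 0) {
            pw <- tw$retweet_count_final + 1L
            orig <- sample.int(n, n_rt, replace = TRUE, prob = pw)
            within <- runif(n_rt) < cfg$within_community_prob
            rt_comm <- integer(n_rt)
            rt_comm[within] <- ci
            if (any(!within) && cfg$n_communities > 1) {
              others <- setdiff(seq_len(cfg$n_communities), ci)
              rt_comm[!within] <- others[
                sample.int(length(others), sum(!within), replace = TRUE)]
            } else {
              rt_comm[!within] <- ci
            }
            rt_auth <- character(n_rt)
            for (cc in sort(unique(rt_comm))) {
              sel <- rt_comm == cc
              rt_auth[sel] <- account_pool[[cc]][
                sample.int(cfg$accounts_per_community, sum(sel),
                           replace = TRUE, prob = zipf_w)]
            }
            rt <- list(
              tweet_id = sprintf("r_%02d_%04d_%05d", ci, d, seq_len(n_rt)),
              author_id = rt_auth,
              community_id = ids[rt_comm],
              timestamp = as.POSIXct(dates[d], tz = "UTC") +
                as.integer(floor(runif(n_rt, 0, 86400))),
              is_retweet = rep(TRUE, n_rt),
              retweeted_id = tw$tweet_id[orig],
              follower_count_at_post = pmax(0L, as.integer(round(
                rlnorm(n_rt, cfg$follower_meanlog, cfg$follower_sdlog)))),
              retweet_count_final = rep(0L, n_rt),
              urls = tw$urls[orig],
              topic_label = tw$topic_label[orig]
            )
            tw <- mapply(c, tw, rt, SIMPLIFY = FALSE)
          }
          tw
        })
    }
  }
  tweets <- data.table::rbindlist(day_tables[seq_len(slot)], use.names = TRUE)
  if (nrow(tweets) == 0) {
    stop_input("generated ecosystem contains no tweets; check baseline_volume")
  }
  data.table::setorder(tweets, timestamp, tweet_id)
  tweets <- as.data.frame(tweets)
  attr(tweets$timestamp, "tzone") <- "UTC"

  # aggregated retweet edges from the stream (retweeter -> original author)
  edges <- build_graph(tweets, as_igraph = FALSE)

  ledger <- ground_truth_ledger(cfg)
  transparency <- synth_transparency(cfg)

  structure(
    list(tweets = tweets,
         edges = edges,
         domains = cfg$domain_pool,
         transparency = transparency,
         ledger = ledger,
         config = cfg),
    class = "ecosystem"
  )
}

#' Ground-truth ledger for an ecosystem configuration
#'
#' One row per (intervention, community): the injected effects on the scales
#' on which downstream analyses report them (odds ratio for volume, relative
#' risk for virality, additive delta for quality). Acceptance and recovery
#' tests read truth from here, never re-deriving it from the stream.
#'
#' @param config an [ecosystem_config()].
#' @return data.frame with columns `intervention`, `community`, `start_date`,
#'   `or_volume`, `rr_virality`, `delta_quality`.
#' @export
ground_truth_ledger <- function(config) {
  rows <- list()
  for (i in seq_along(config$interventions)) {
    iv <- config$interventions[[i]]
    rows[[i]] <- data.frame(
      intervention = i,
      community = iv$communities,
      start_date = iv$start_date,
      or_volume = iv$effect_on_volume,
      rr_virality = iv$effect_on_virality,
      delta_quality = iv$effect_on_quality,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(intervention = integer(0), community = character(0),
                      start_date = as.Date(character(0)),
                      or_volume = numeric(0), rr_virality = numeric(0),
                      delta_quality = numeric(0)))
  }
  do.call(rbind, rows)
}

# Monthly transparency counts: moderation intensity ramps up once the first
# intervention is active, with mild log-normal month-to-month noise.
synth_transparency <- function(cfg) {
  months <- unique(month_key(seq(cfg$start_date, by = "day",
                                 length.out = cfg$days)))
  starts <- as.Date(vapply(cfg$interventions,
                           function(iv) format(iv$start_date), character(1)))
  first_start <- if (length(starts) > 0) min(starts) else NA
  with_seed(substream_seed(cfg$seed, "transparency"), {
    intensity <- vapply(months, function(m) {
      m1 <- as.Date(paste0(m, "-01"))
      if (!is.na(first_start) && m1 >= as.Date(format(first_start, "%Y-%m-01")))
        1 else 0.2
    }, numeric(1))
    data.frame(
      month = months,
      content_removed = as.integer(round(
        4000 * intensity * rlnorm(length(months), 0, 0.2))),
      accounts_suspended = as.integer(round(
        300 * intensity * rlnorm(length(months), 0, 0.25))),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a planted-partition retweet graph
#'
#' Builds a weighted directed retweet graph with planted community structure
#' and preferential-attachment-style hubs: retweet events pick an author
#' within the retweeter's community with probability `within_community_prob`
#' under Zipf (rich-get-richer) account weights, otherwise a random other
#' community. Weights are positive integer retweet counts.
#'
#' @param config an [ecosystem_config()] with at least 2 communities.
#' @param events number of retweet events to draw (default
#'   `20 x total accounts`).
#' @return data.frame edge list `source`, `target`, `weight` (aggregated,
#'   no self-loops).
#' @export
generate_retweet_graph <- function(config, events = NULL) {
  cfg <- config
  if (cfg$n_communities < 2) {
    stop_input("n_communities must be >= 2 to generate a retweet graph")
  }
  n_acc <- cfg$accounts_per_community
  total <- cfg$n_communities * n_acc
  if (total < 2) return(data.frame(source = character(0),
                                   target = character(0),
                                   weight = integer(0)))
  if (is.null(events)) events <- 20L * total
  pool <- lapply(seq_len(cfg$n_communities), function(ci) {
    sprintf("user_%02d_%04d", ci, seq_len(n_acc))
  })
  zipf_w <- 1 / seq_len(n_acc)
  comm_w <- cfg$baseline_volume / sum(cfg$baseline_volume)
  with_seed(substream_seed(cfg$seed, "graph"), {
    src_comm <- sample.int(cfg$n_communities, events, replace = TRUE,
                           prob = comm_w)
    src_idx <- sample.int(n_acc, events, replace = TRUE, prob = zipf_w)
    within <- runif(events) < cfg$within_community_prob
    dst_comm <- src_comm
    if (any(!within)) {
      shift <- sample.int(cfg$n_communities - 1L, sum(!within), replace = TRUE)
      dst_comm[!within] <- 1L +
        (src_comm[!within] - 1L + shift) %% cfg$n_communities
    }
    dst_idx <- sample.int(n_acc, events, replace = TRUE, prob = zipf_w)
    src <- mapply(function(c, i) pool[[c]][i], src_comm, src_idx)
    dst <- mapply(function(c, i) pool[[c]][i], dst_comm, dst_idx)
    keep <- src != dst
    dt <- data.table::data.table(source = src[keep], target = dst[keep])
    agg <- dt[, list(weight = .N), by = c("source", "target")]
    data.table::setorder(agg, source, target)
    as.data.frame(agg)
  })
}

#' @export
print.ecosystem <- function(x, ...) {
  cat("<ecosystem>", nrow(x$tweets), "tweet records,",
      x$config$n_communities, "communities,",
      x$config$days, "days from", format(x$config$start_date), "\n")
  cat("  interventions:", length(x$config$interventions),
      " | outage days:", length(x$config$outage_days), "\n")
  invisible(x)
}
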