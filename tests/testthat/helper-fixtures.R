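# Hand-built tweet streams and small config factories used across tests.

# one tweet record row; defaults give a plain user-authored tweet
tweet_row <- function(id, author = "u1", community = "community_01",
                      day = as.Date("2020-03-01"), secs = 0,
                      is_retweet = FALSE, retweeted_id = NA_character_,
                      followers = 100L, retweets = 0L, urls = "",
                      topic = NA_character_) {
  data.frame(
    tweet_id = id, author_id = author, community_id = community,
    timestamp = as.POSIXct(day, tz = "UTC") + secs,
    is_retweet = is_retweet, retweeted_id = retweeted_id,
    follower_count_at_post = followers, retweet_count_final = retweets,
    urls = urls, topic_label = topic,
    stringsAsFactors = FALSE
  )
}

# n user tweets per (community, day) according to a named count list:
# counts = list("community_01" = c(day1 = 5, day2 = 3), ...)
counted_stream <- function(counts, start = as.Date("2020-03-01")) {
  rows <- list()
  for (cid in names(counts)) {
    v <- counts[[cid]]
    for (d in seq_along(v)) {
      n <- v[d]
      if (n == 0) next
      for (i in seq_len(n)) {
        rows[[length(rows) + 1L]] <- tweet_row(
          sprintf("%s_d%03d_%04d", cid, d, i),
          author = paste0(cid, "_a", (i %% 3) + 1),
          community = cid, day = start + d - 1, secs = i)
      }
    }
  }
  do.call(rbind, rows)
}

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_communities = 2, days = 30, baseline_volume = 20,
                   accounts_per_community = 8, seed = 1)
  do.call(ecosystem_config, utils::modifyList(defaults, args))
}

# naive repeated-removal k-core oracle on an undirected neighbour basis
naive_k_core_nodes <- function(edges, k) {
  if (nrow(edges) == 0) return(character(0))
  nodes <- unique(c(edges$source, edges$target))
  repeat {
    pairs <- unique(rbind(
      data.frame(a = edges$source, b = edges$target,
                 stringsAsFactors = FALSE),
      data.frame(a = edges$target, b = edges$source,
                 stringsAsFactors = FALSE)))
    pairs <- pairs[pairs$a %in% nodes & pairs$b %in% nodes, ]
    pairs <- pairs[pairs$a != pairs$b, ]
    deg <- table(factor(pairs$a, levels = nodes))
    low <- nodes[deg < k]
    if (length(low) == 0 || length(nodes) == 0) break
    nodes <- setdiff(nodes, low)
  }
  sort(nodes)
}

# random directed weighted edge list on n nodes
random_edges <- function(n, p = 0.08) {
  pairs <- expand.grid(source = seq_len(n), target = seq_len(n))
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < p
  el <- pairs[keep, ]
  if (nrow(el) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      weight = integer(0)))
  }
  data.frame(source = paste0("n", el$source),
             target = paste0("n", el$target),
             weight = sample(1:4, nrow(el), replace = TRUE),
             stringsAsFactors = FALSE)
}
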