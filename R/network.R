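#' Build the weighted retweet network from a tweet stream
#'
#' Each account is a node; an arc runs from the retweeting account to the
#' original author (information credit flows to the author), weighted by the
#' total number of retweets between the ordered pair. Retweet records whose
#' original tweet is absent from the stream are dropped and their count
#' logged; self-retweets are removed.
#'
#' @param tweets tweet data.frame.
#' @param as_igraph return a directed weighted [igraph::graph] (`TRUE`) or
#'   the edge-list data.frame `source`, `target`, `weight`.
#' @return Graph or edge list; the number of unresolvable retweets is
#'   attached as attribute `n_orphans`.
#' @export
build_graph <- function(tweets, as_igraph = FALSE) {
  assert_columns(tweets, c("tweet_id", "author_id", "is_retweet",
                           "retweeted_id"), "tweet stream")
  rt <- tweets[tweets$is_retweet, ]
  authors <- stats::setNames(tweets$author_id, tweets$tweet_id)
  empty <- data.frame(source = character(0), target = character(0),
                      weight = integer(0))
  if (nrow(rt) == 0) {
    edges <- empty
    attr(edges, "n_orphans") <- 0L
  } else {
    orig_author <- unname(authors[rt$retweeted_id])
    orphan <- is.na(orig_author)
    n_orphans <- sum(orphan)
    if (n_orphans > 0) {
      message(n_orphans, " retweet record(s) with unresolvable original ",
              "author dropped")
    }
    dt <- data.table::data.table(source = rt$author_id[!orphan],
                                 target = orig_author[!orphan])
    dt <- dt[dt$source != dt$target, ]
    if (nrow(dt) == 0) {
      edges <- empty
    } else {
      agg <- dt[, list(weight = .N), by = c("source", "target")]
      data.table::setorder(agg, source, target)
      edges <- as.data.frame(agg)
    }
    attr(edges, "n_orphans") <- n_orphans
  }
  if (!as_igraph) return(edges)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  igraph::E(g)$weight <- edges$weight
  attr(g, "n_orphans") <- attr(edges, "n_orphans")
  g
}

as_graph <- function(x) {
  if (inherits(x, "igraph")) return(x)
  g <- igraph::graph_from_data_frame(x, directed = TRUE)
  if (!is.null(x$weight)) igraph::E(g)$weight <- x$weight
  g
}

#' k-core decomposition of a retweet network
#'
#' Returns the maximal subgraph in which every node is connected to at least
#' `k` distinct other nodes, by iterative peeling to a fixpoint. The degree
#' test treats the graph as undirected and ignores arc multiplicity and --
#' by default -- weights; `weighted = TRUE` peels on weighted degree
#' instead.
#'
#' @param graph igraph object or edge-list data.frame.
#' @param k minimum number of neighbours (default 3).
#' @param weighted peel on summed arc weight instead of distinct-neighbour
#'   count.
#' @return The induced igraph subgraph (possibly empty).
#' @export
k_core <- function(graph, k = 3, weighted = FALSE) {
  if (k < 1) stop_input("k must be >= 1")
  g <- as_graph(graph)
  und <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "sum"))
  und <- igraph::simplify(und, edge.attr.comb = list(weight = "sum"))
  if (!weighted) {
    keep <- igraph::coreness(und) >= k
  } else {
    # iterative peeling on weighted degree
    keep <- rep(TRUE, igraph::vcount(und))
    repeat {
      sub <- igraph::induced_subgraph(und, which(keep))
      deg <- igraph::strength(sub)
      low <- deg < k
      if (!any(low)) break
      keep[which(keep)[low]] <- FALSE
      if (!any(keep)) break
    }
  }
  igraph::induced_subgraph(g, which(keep))
}

#' Louvain community detection on a retweet network
#'
#' Runs modularity-maximising Louvain clustering on the (collapsed,
#' undirected, weighted) graph, deterministically for a given seed.
#' A graph with no edges yields one community per node, with a warning.
#'
#' @param graph igraph object or edge-list data.frame (typically the 3-core
#'   of the retweet network).
#' @param resolution Louvain resolution parameter (1.0 default).
#' @param seed integer seed.
#' @return An object of class `community_partition`: data.frame
#'   `account_id`, `community_id`, plus `modularity` and the igraph
#'   communities object as attributes.
#' @export
detect_communities <- function(graph, resolution = 1.0, seed = 1L) {
  g <- as_graph(graph)
  if (igraph::vcount(g) == 0) stop_input("empty graph")
  und <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "sum"))
  if (igraph::ecount(und) == 0) {
    warning("graph has no edges; one community per node")
    membership <- seq_len(igraph::vcount(und))
    part <- data.frame(account_id = igraph::V(und)$name,
                       community_id = sprintf("community_%02d", membership),
                       stringsAsFactors = FALSE)
    attr(part, "modularity") <- 0
    class(part) <- c("community_partition", "data.frame")
    return(part)
  }
  cl <- with_seed(seed, igraph::cluster_louvain(und, resolution = resolution))
  membership <- igraph::membership(cl)
  part <- data.frame(account_id = igraph::V(und)$name,
                     community_id = sprintf("community_%02d",
                                            as.integer(membership)),
                     stringsAsFactors = FALSE)
  attr(part, "modularity") <- igraph::modularity(und, membership,
                                                 weights = igraph::E(und)$weight)
  class(part) <- c("community_partition", "data.frame")
  part
}

#' Inter-community flows and most-active account lists
#'
#' Sums arc weights between (and within) communities into a flow matrix and
#' ranks each community's accounts by activity, keeping the top 25 (the
#' lists used to label communities). Activity is the account's tweet count
#' when a stream is supplied, otherwise its total arc weight; ties break
#' lexicographically.
#'
#' @param graph igraph object or edge-list data.frame.
#' @param partition `community_partition` (or data.frame `account_id`,
#'   `community_id`).
#' @param tweets optional tweet stream for tweet-count activity ranking.
#' @param top_n accounts retained per community (default 25).
#' @return list with `flows` (community x community weight matrix) and
#'   `top_accounts` (named list of character vectors).
#' @export
community_flows <- function(graph, partition, tweets = NULL, top_n = 25) {
  g <- as_graph(graph)
  assert_columns(partition, c("account_id", "community_id"), "partition")
  comm <- stats::setNames(partition$community_id, partition$account_id)
  el <- igraph::as_data_frame(g, what = "edges")
  ids <- sort(unique(partition$community_id))
  flows <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(el) > 0) {
    sc <- comm[el$from]
    tc <- comm[el$to]
    ok <- !is.na(sc) & !is.na(tc)
    if (any(ok)) {
      agg <- tapply(el$weight[ok], list(sc[ok], tc[ok]), sum)
      flows[rownames(agg), colnames(agg)] <-
        ifelse(is.na(agg), 0, agg)
    }
  }
  activity <- if (!is.null(tweets)) {
    tab <- table(tweets$author_id)
    stats::setNames(as.numeric(tab), names(tab))
  } else {
    stats::setNames(igraph::strength(g), igraph::V(g)$name)
  }
  top_accounts <- lapply(ids, function(cid) {
    acc <- partition$account_id[partition$community_id == cid]
    act <- activity[acc]
    act[is.na(act)] <- 0
    ord <- order(-act, acc)   # ties break lexicographically
    head(acc[ord], top_n)
  })
  names(top_accounts) <- ids
  list(flows = flows, top_accounts = top_accounts)
}

#' Write a community partition to CSV
#'
#' @param partition `community_partition`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  write.csv(as.data.frame(partition)[, c("account_id", "community_id")],
            path, row.names = FALSE)
  invisible(path)
}
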