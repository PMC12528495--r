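#' Read and write tweet streams
#'
#' Tweet streams are exchanged either as JSON-lines (one record per line,
#' `urls` as a JSON array, UTC ISO-8601 timestamps) or as CSV with identical
#' columns (`urls` space-separated). The in-memory representation is a
#' data.frame with columns `tweet_id`, `author_id`, `community_id`,
#' `timestamp` (POSIXct, UTC), `is_retweet`, `retweeted_id`,
#' `follower_count_at_post`, `retweet_count_final`, `urls` (space-separated
#' string, `""` if none), `topic_label`.
#'
#' @param tweets tweet data.frame.
#' @param path file path; format inferred from the extension (`.jsonl`/
#'   `.ndjson` vs `.csv`) unless `format` is given.
#' @param format `"jsonl"` or `"csv"`.
#' @return `read_tweet_stream()` returns the tweet data.frame;
#'   `write_tweet_stream()` returns `path` invisibly.
#' @export
write_tweet_stream <- function(tweets, path, format = NULL) {
  format <- format %||% infer_stream_format(path)
  df <- tweets
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (format == "jsonl") {
    recs <- df
    recs$urls <- lapply(strsplit(df$urls, " ", fixed = TRUE),
                        function(u) u[nzchar(u)])
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(vapply(seq_len(nrow(recs)), function(i) {
      jsonlite::toJSON(lapply(recs[i, , drop = FALSE], function(col) {
        if (is.list(col)) col[[1]] else col
      }), auto_unbox = TRUE, null = "null", na = "null")
    }, character(1)), con)
  } else {
    write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

infer_stream_format <- function(path) {
  if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE)) "jsonl"
  else "csv"
}

#' @rdname write_tweet_stream
#' @export
read_tweet_stream <- function(path, format = NULL) {
  format <- format %||% infer_stream_format(path)
  if (format == "jsonl") {
    lines <- readLines(path)
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- data.table::rbindlist(lapply(recs, function(r) {
      r$urls <- paste(unlist(r$urls), collapse = " ")
      r$retweeted_id <- r$retweeted_id %||% NA_character_
      r$topic_label <- r$topic_label %||% NA_character_
      as.data.frame(r, stringsAsFactors = FALSE)
    }), use.names = TRUE, fill = TRUE)
    df <- as.data.frame(df)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(tweet_id = "character",
                                  author_id = "character",
                                  retweeted_id = "character"),
                   na.strings = "")
    df$urls[is.na(df$urls)] <- ""
  }
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%SZ")
  df$is_retweet <- as.logical(df$is_retweet)
  if (is.null(df$urls)) df$urls <- ""
  df
}

#' Read and write weighted edge lists
#'
#' Edge lists travel as TSV `source<TAB>target<TAB>weight`.
#'
#' @param edges data.frame `source`, `target`, `weight`.
#' @param path file path.
#' @return the edge data.frame, or `path` invisibly for the writer.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  read.csv(path, sep = "\t", stringsAsFactors = FALSE,
           colClasses = c(source = "character", target = "character"))
}

#' Read and write domain-quality tables
#'
#' CSV `domain,quality` with ratings in \[0, 1\]; domains are lower-cased and
#' must be unique.
#'
#' @param domains data.frame `domain`, `quality`.
#' @param path file path.
#' @return the domain table, or `path` invisibly for the writer.
#' @export
write_domain_table <- function(domains, path) {
  write.csv(domains, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_domain_table
#' @export
read_domain_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("domain", "quality"), "domain table")
  df$domain <- tolower(df$domain)
  if (anyDuplicated(df$domain)) stop_input("domain table: duplicate domains")
  if (any(df$quality < 0 | df$quality > 1)) {
    stop_input("domain table: quality ratings must lie in [0, 1]")
  }
  df
}

#' Read and write monthly transparency tables
#'
#' CSV `month,content_removed,accounts_suspended`, months as `YYYY-MM`.
#'
#' @param transparency data.frame.
#' @param path file path.
#' @return the table, or `path` invisibly for the writer.
#' @export
write_transparency_table <- function(transparency, path) {
  write.csv(transparency, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transparency_table
#' @export
read_transparency_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(month = "character"))
  assert_columns(df, c("month", "content_removed", "accounts_suspended"),
                 "transparency table")
  df
}

#' Write a ground-truth ledger as YAML
#'
#' @param ledger data.frame from [ground_truth_ledger()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  lst <- lapply(seq_len(nrow(ledger)), function(i) {
    row <- ledger[i, ]
    list(intervention = row$intervention,
         community = row$community,
         start_date = format(row$start_date),
         or_volume = row$or_volume,
         rr_virality = row$rr_virality,
         delta_quality = row$delta_quality)
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Write an ecosystem's artifacts to a directory
#'
#' Emits `tweets.jsonl` (or `.csv`), `edges.tsv`, `domains.csv`,
#' `transparency.csv`, and `ledger.yaml`.
#'
#' @param eco an `ecosystem` from [generate_ecosystem()].
#' @param dir output directory (created if needed).
#' @param stream_format `"jsonl"` or `"csv"`.
#' @return named character vector of paths, invisibly.
#' @export
write_ecosystem <- function(eco, dir, stream_format = "csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (stream_format == "jsonl") "jsonl" else "csv"
  paths <- c(
    tweets = file.path(dir, paste0("tweets.", ext)),
    edges = file.path(dir, "edges.tsv"),
    domains = file.path(dir, "domains.csv"),
    transparency = file.path(dir, "transparency.csv"),
    ledger = file.path(dir, "ledger.yaml")
  )
  write_tweet_stream(eco$tweets, paths[["tweets"]], format = stream_format)
  write_edge_list(eco$edges, paths[["edges"]])
  write_domain_table(eco$domains, paths[["domains"]])
  write_transparency_table(eco$transparency, paths[["transparency"]])
  write_ledger(eco$ledger, paths[["ledger"]])
  invisible(paths)
}
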