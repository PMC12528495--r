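#' Run the end-to-end synthetic moderation-evaluation pipeline
#'
#' Orchestrates the declared stages in dependency order -- `synth` (generate
#' the ecosystem), `preprocess` (outage detection), `measures` (daily and
#' monthly panels), `network` (retweet graph, 3-core, Louvain communities),
#' `cits` (paired counterfactual inference), `lsdv` (monthly fixed-effects
#' regression) -- writing every artifact plus a YAML run manifest into
#' `out_dir`. Deterministic stages are byte-stable for a fixed seed and
#' config.
#'
#' @param config a list (or path to a YAML file) with optional entries:
#'   `stages` (character subset, default all), `synth` (arguments for
#'   [ecosystem_config()], with `interventions` given as lists of fields of
#'   [intervention_spec()]), `cits` (`pairs` data.frame or list,
#'   `eval_phases`, `B`, `alpha`, `pooling`, `order`, `period`, `measures`),
#'   `lsdv` (`measure`, `hac_lags`), `phases` (data.frame or YAML path).
#' @param out_dir output directory.
#' @param seed root seed; overrides `config$seed`.
#' @return list of in-memory artifacts plus `manifest`, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("modcits_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  stages <- config$stages %||%
    c("synth", "preprocess", "measures", "network", "cits", "lsdv")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    message(msg)
  }
  artifacts <- list()
  paths <- character(0)

  synth_args <- config$synth %||% list()
  if (!is.null(synth_args$interventions)) {
    synth_args$interventions <- lapply(synth_args$interventions, function(iv) {
      if (inherits(iv, "intervention_spec")) iv else do.call(intervention_spec, iv)
    })
  }
  if (!is.null(synth_args$start_date)) {
    synth_args$start_date <- as.Date(synth_args$start_date)
  }
  if (!is.null(synth_args$outage_days)) {
    synth_args$outage_days <- as.Date(unlist(synth_args$outage_days))
  }
  synth_args$seed <- seed
  cfg <- do.call(ecosystem_config, synth_args)

  if ("cits" %in% stages && is.null(config$cits$pairs)) {
    stop_input("config error: cits stage requires cits$pairs")
  }
  need_domains <- any(c("measures", "cits", "lsdv") %in% stages)
  if (need_domains && is.null(cfg$domain_pool)) {
    stop_input("config error: quality measures requested without a domain table")
  }

  eco <- generate_ecosystem(cfg)
  artifacts$ecosystem <- eco
  if ("synth" %in% stages) {
    paths <- c(paths, write_ecosystem(eco, out_dir))
  }

  report <- NULL
  if (any(c("preprocess", "measures", "cits", "lsdv") %in% stages)) {
    report <- detect_outages(eco$tweets)
    p <- file.path(out_dir, "outage_report.yaml")
    write_outage_report(report, p)
    paths <- c(paths, p)
    artifacts$outages <- report
  }

  if (any(c("measures", "cits", "lsdv") %in% stages)) {
    daily <- build_measures(eco$tweets, domains = eco$domains,
                            dropped = report)
    daily <- impute_measures(daily, report)
    monthly <- monthly_aggregate(eco$tweets, domains = eco$domains)
    artifacts$daily <- daily
    artifacts$monthly <- monthly
    p1 <- file.path(out_dir, "measures_daily.csv")
    p2 <- file.path(out_dir, "measures_monthly.csv")
    write.csv(daily, p1, row.names = FALSE)
    write.csv(monthly, p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
  }

  if ("network" %in% stages) {
    g <- build_graph(eco$tweets, as_igraph = TRUE)
    core <- k_core(g, k = 3)
    if (igraph::vcount(core) > 0) {
      part <- detect_communities(core, seed = substream_seed(seed, "louvain"))
      fl <- community_flows(core, part, tweets = eco$tweets)
      artifacts$partition <- part
      artifacts$flows <- fl
      p <- file.path(out_dir, "partition.csv")
      write_partition(part, p)
      pf <- file.path(out_dir, "flows.csv")
      write.csv(as.data.frame(fl$flows), pf, row.names = TRUE)
      paths <- c(paths, p, pf)
    } else {
      note("network stage: 3-core is empty; partition skipped")
    }
    artifacts$graph <- g
  }

  phases <- config$phases %||% default_policy_phases()
  if (is.character(phases)) phases <- read_phase_table(phases)
  if (is.list(phases) && !is.data.frame(phases)) {
    phases <- do.call(rbind, lapply(phases, function(r) {
      data.frame(phase = r$phase, start = as.Date(r$start),
                 end = as.Date(r$end), stringsAsFactors = FALSE)
    }))
  }

  if ("cits" %in% stages) {
    cc <- config$cits
    pairs <- cc$pairs
    if (!is.data.frame(pairs)) {
      pairs <- do.call(rbind, lapply(pairs, function(p) {
        data.frame(treated = p$treated, comparator = p$comparator,
                   stringsAsFactors = FALSE)
      }))
    }
    effects <- run_cits(
      artifacts$daily, pairs, phases = phases,
      eval_phases = cc$eval_phases %||% "five_strikes",
      measures = cc$measures,
      alpha = cc$alpha %||% 0.05, B = cc$B %||% 1000,
      seed = substream_seed(seed, "cits"),
      pooling = cc$pooling %||% "sum",
      order = cc$order %||% "auto",
      period = cc$period %||% 7)
    artifacts$effects <- effects
    p <- file.path(out_dir, "effects.csv")
    write.csv(effects, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  if ("lsdv" %in% stages) {
    lc <- config$lsdv %||% list()
    pan <- build_panel(artifacts$monthly, eco$transparency,
                       measure = lc$measure %||% "content_logit")
    fit <- fit_lsdv(pan, hac_lags = lc$hac_lags %||% "auto")
    adf <- residual_stationarity(fit)
    artifacts$lsdv <- fit
    artifacts$lsdv_adf <- adf
    p <- file.path(out_dir, "lsdv_coefficients.csv")
    write.csv(fit$coef, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  manifest <- list(
    subcommand = paste(stages, collapse = "+"),
    seed = seed,
    config_hash = config_hash(config),
    software_version = as.character(utils::packageVersion("modcits")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    inputs = as.list(tools::md5sum(paths[file.exists(paths)])),
    warnings = as.list(warnings_log)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  artifacts$manifest <- manifest
  artifacts$out_dir <- out_dir
  invisible(artifacts)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
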