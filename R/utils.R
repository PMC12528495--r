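#' @importFrom stats arima rnorm rpois rlnorm rnbinom runif qnorm pnorm dnorm
#'   lm coef residuals complete.cases sd var quantile Box.test uniroot
#'   na.omit aggregate setNames pacf acf plogis qlogis approx
#' @importFrom utils head tail write.csv read.csv packageVersion
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic substream seeds
#'
#' Derives a 31-bit seed from a root seed and a sequence of string or integer
#' keys, by polynomial rolling hash modulo the Mersenne prime 2^31 - 1. Every
#' source of randomness in the package draws its seed through this function,
#' so that any stage (a single community-day of the generator, one
#' counterfactual simulation of one pair/phase/measure cell) can be
#' regenerated in isolation.
#'
#' @param root integer root seed.
#' @param ... character or integer keys naming the substream, e.g.
#'   `substream_seed(7, "volume", "community_03")`.
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "volume", 3) != substream_seed(1, "volume", 4)
substream_seed <- function(root, ...) {
  m <- 2147483647
  h <- as.numeric(root) %% m
  for (key in list(...)) {
    for (code in utf8ToInt(paste0("/", as.character(key)))) {
      h <- (h * 131 + code) %% m
    }
  }
  as.integer(h %% (m - 2L) + 1L)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Logit and inverse logit
#'
#' Thin wrappers over [stats::qlogis()] / [stats::plogis()], exported because
#' every proportion-type outcome in the package lives on the logit scale.
#'
#' @param p proportion in (0, 1).
#' @param x real number.
#' @return `logit()` returns log(p / (1 - p)); `inv_logit()` its inverse.
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

# month key "YYYY-MM" from a Date
month_key <- function(date) format(as.Date(date), "%Y-%m")

month_key_seq <- function(from, to) {
  f <- as.Date(paste0(from, "-01"))
  t <- as.Date(paste0(to, "-01"))
  format(seq(f, t, by = "month"), "%Y-%m")
}

# consecutive-run grouping of sorted integer-like values
run_groups <- function(x) {
  x <- sort(unique(x))
  if (length(x) == 0) return(integer(0))
  cumsum(c(1L, diff(x) != 1))
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_input(sprintf("%s is missing required column(s): %s",
                       what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
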