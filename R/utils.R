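# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never disturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Draw from a normal truncated to [a, b] by inverse-CDF
#' @noRd
rtruncnorm <- function(n, mean, sd, a, b) {
  pa <- stats::pnorm(a, mean, sd)
  pb <- stats::pnorm(b, mean, sd)
  u <- stats::runif(n, pa, pb)
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, a), b) # guard against qnorm slop at extreme tails
}

#' Mean of a normal truncated to [a, b]
#' @noRd
truncnorm_mean <- function(mean, sd, a, b) {
  alpha <- (a - mean) / sd
  beta <- (b - mean) / sd
  z <- stats::pnorm(beta) - stats::pnorm(alpha)
  if (z < 1e-300) # truncation window numerically in a far tail
    return(if (mean < a) a else if (mean > b) b else (a + b) / 2)
  mean + sd * (stats::dnorm(alpha) - stats::dnorm(beta)) / z
}

#' Location parameter so the truncated-normal mean hits a target
#'
#' Solves for mu such that the mean of N(mu, sd) truncated to [a, b]
#' equals `target`. Used to keep generated marginal means on calibration.
#' @noRd
truncnorm_location <- function(target, sd, a, b) {
  stopifnot(target > a, target < b)
  f <- function(mu) truncnorm_mean(mu, sd, a, b) - target
  width <- 1
  repeat { # expand until the bracket straddles the target
    lo <- a - width * sd
    hi <- b + width * sd
    if (f(lo) < 0 && f(hi) > 0) break
    width <- width + 1
    if (width > 8) stop("cannot calibrate truncated-normal location")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Full calendar years elapsed between two dates
#' @noRd
full_years_between <- function(from, to) {
  from <- as.POSIXlt(as.Date(from))
  to <- as.POSIXlt(as.Date(to))
  years <- to$year - from$year
  before_anniversary <- (to$mon < from$mon) |
    (to$mon == from$mon & to$mday < from$mday)
  as.integer(years - before_anniversary)
}

#' English weekday name, locale-independent
#' @noRd
weekday_name <- function(dates) {
  wd <- as.POSIXlt(as.Date(dates))$wday # 0 = Sunday
  c("Sunday", "Monday", "Tuesday", "Wednesday",
    "Thursday", "Friday", "Saturday")[wd + 1L]
}

#' Write a data.frame as CSV with "" for NA (the package-wide convention)
#' @noRd
write_table_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (inherits(df[[j]], "Date")) df[[j]] <- format(df[[j]], "%Y-%m-%d")
    if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a CSV written by write_table_csv
#' @noRd
read_table_csv <- function(path, colClasses = NA) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  colClasses = colClasses, check.names = FALSE)
}

#' Atomic file write: write to a temp sibling, then rename
#' @noRd
write_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
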