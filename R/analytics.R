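# Analytics over the warehouse: regression-weighted individual indexes,
# unweighted global indexes, sliced breakdowns, user change history, and
# file-based report export.

#' Regression-weighted individual index at a date
#'
#' Fits an ordinary-least-squares line of index value on time (integer days
#' since the user's first observation) over the supplied series and returns
#' the line's value at the query date, clamped to the `[-5, 5]` index
#' scale. Outlying single measurements are thereby damped and the reported
#' value reflects the user's whole history. A single point returns its own
#' value. Callers that must not look ahead (e.g. the running trend in
#' [export_report()]) pass only the points observed up to the query date.
#'
#' @param history Data.frame with columns `date` and `index_value`; dates
#'   unique per series.
#' @param query_date Date at which the trend line is evaluated; must not
#'   precede the earliest point.
#' @return The weighted index, a single number in `[-5, 5]`.
#' @examples
#' h <- data.frame(date = as.Date("2019-01-01") + c(0, 10),
#'                 index_value = c(2, 4))
#' weighted_index(h, as.Date("2019-01-06"))
#' @export
weighted_index <- function(history, query_date) {
  history <- as.data.frame(history)
  stopifnot(all(c("date", "index_value") %in% names(history)))
  if (!nrow(history)) stop("history must contain at least one point")
  d <- as.Date(history$date)
  if (anyDuplicated(d)) stop("dates must be unique within a user series")
  query_date <- as.Date(query_date)
  if (query_date < min(d)) stop("query_date precedes the earliest point")
  v <- history$index_value
  t <- as.numeric(d - min(d))
  tq <- as.numeric(query_date - min(d))
  if (length(v) == 1L) return(min(5, max(-5, v)))
  mt <- mean(t); mv <- mean(v)
  sxx <- sum((t - mt)^2)
  slope <- if (sxx > 0) sum((t - mt) * (v - mv)) / sxx else 0
  pred <- mv + slope * (tq - mt)
  min(5, max(-5, pred))
}

# Fact table joined with the dimensions, exposing the sliceable attributes.
fact_view <- function(wh) {
  fact <- wh_read(wh, "fact")
  dim_user <- wh_read(wh, "dim_user")
  dim_district <- wh_read(wh, "dim_district")
  dim_cal <- wh_read(wh, "dim_calendar")
  v <- merge(fact, dim_user[, c("id_user", "district", "gender")],
             by = "id_user", all.x = TRUE, suffixes = c("", "_user"))
  v <- merge(v, dim_district[, c("code", "region")],
             by.x = "district", by.y = "code", all.x = TRUE)
  v <- merge(v, dim_cal[, c("date", "year", "month", "day", "weekday")],
             by.x = "index_date", by.y = "date", all.x = TRUE)
  v
}

slice_dimensions <- function() {
  c("gender", "region", "district", "weekday", "year", "month", "day")
}

#' Global (unweighted) index over a slice of the fact table
#'
#' The arithmetic mean of the raw stored index values, optionally
#' restricted to one category of a declared slicing dimension. An empty
#' slice yields `NA` (an explicit no-data marker), never 0.
#'
#' @param wh A `cwb_warehouse`.
#' @param dimension Optional one of
#'   `gender, region, district, weekday, year, month, day`.
#' @param value Optional filter value for `dimension`.
#' @return A single number in `[-5, 5]`, or `NA_real_` for an empty slice.
#' @export
global_index <- function(wh, dimension = NULL, value = NULL) {
  v <- fact_view(wh)
  if (!is.null(dimension)) {
    if (!dimension %in% slice_dimensions())
      stop("unknown slicing dimension: ", dimension)
    if (!is.null(value)) v <- v[!is.na(v[[dimension]]) &
                                  v[[dimension]] == value, , drop = FALSE]
  }
  if (!nrow(v)) return(NA_real_)
  mean(v$index_value)
}

#' Per-category breakdown of the global index
#'
#' One row per observed category of the dimension, with the category's
#' unweighted mean index, its colour band and its fact count. The
#' count-weighted category means reconstruct the unsliced global index.
#'
#' @param wh A `cwb_warehouse`.
#' @param dimension One of the declared slicing dimensions.
#' @return Data.frame with columns `category`, `index`, `colour`, `n`.
#' @export
breakdown <- function(wh, dimension) {
  if (!dimension %in% slice_dimensions())
    stop("unknown slicing dimension: ", dimension)
  v <- fact_view(wh)
  if (!nrow(v))
    return(data.frame(category = character(0), index = numeric(0),
                      colour = character(0), n = integer(0)))
  g <- v[[dimension]]
  agg <- stats::aggregate(v$index_value, by = list(category = g), FUN = mean)
  cnt <- stats::aggregate(v$index_value, by = list(category = g),
                          FUN = length)
  out <- data.frame(category = as.character(agg$category),
                    index = agg$x,
                    colour = as.character(colour_of(agg$x)),
                    n = as.integer(cnt$x), stringsAsFactors = FALSE)
  out[order(out$category), , drop = FALSE]
}

#' History of a user's tracked record changes
#'
#' Chronological old-to-new changes of education level, residence district
#' and salary band reconstructed from the type-4 history table.
#'
#' @param wh A `cwb_warehouse`.
#' @param user_id A user present in the user dimension.
#' @return Data.frame with columns `date`, `attribute`, `old`, `new`;
#'   empty (zero rows) for a user with no changes.
#' @export
history_report <- function(wh, user_id) {
  dim <- wh_read(wh, "dim_user")
  if (!user_id %in% dim$id_user) stop("unknown user: ", user_id)
  hst <- wh_read(wh, "dim_user_hst")
  h <- hst[hst$id_user == user_id, , drop = FALSE]
  h <- h[order(h$valid_from), , drop = FALSE]
  out <- data.frame(date = character(0), attribute = character(0),
                    old = character(0), new = character(0),
                    stringsAsFactors = FALSE)
  tracked <- c(district = "residence", education = "education",
               salary = "salary")
  if (nrow(h) < 2L) return(out)
  for (i in 2:nrow(h)) {
    for (f in names(tracked)) {
      if (!identical(h[[f]][i - 1L], h[[f]][i])) {
        out <- rbind(out, data.frame(date = h$valid_from[i],
                                     attribute = unname(tracked[f]),
                                     old = h[[f]][i - 1L],
                                     new = h[[f]][i],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$date, out$attribute), , drop = FALSE]
}

#' Export the warehouse reports as CSV files
#'
#' Writes the three report products: a per-user trend file (each stored
#' index with its running regression-weighted index and colour), a global
#' file (the overall index plus per-category breakdowns for gender,
#' region, weekday, year and month), and a history file (all users' tracked
#' record changes). Empty warehouses yield valid header-only files.
#'
#' @param wh A `cwb_warehouse`.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the written file paths.
#' @export
export_report <- function(wh, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fact <- wh_read(wh, "fact")

  trend <- data.frame(id_user = integer(0), date = character(0),
                      index_value = numeric(0), weighted_index = numeric(0),
                      colour = character(0), stringsAsFactors = FALSE)
  if (nrow(fact)) {
    fact <- fact[order(fact$id_user, fact$index_date), , drop = FALSE]
    pieces <- lapply(split(fact, fact$id_user), function(f) {
      h <- data.frame(date = f$index_date, index_value = f$index_value)
      w <- vapply(seq_len(nrow(f)),
                  function(i) weighted_index(h[seq_len(i), , drop = FALSE],
                                             f$index_date[i]),
                  numeric(1))
      data.frame(id_user = f$id_user, date = f$index_date,
                 index_value = f$index_value,
                 weighted_index = round(w, 4),
                 colour = as.character(colour_of(w)),
                 stringsAsFactors = FALSE)
    })
    trend <- do.call(rbind, pieces)
    rownames(trend) <- NULL
  }

  overall <- global_index(wh)
  global <- data.frame(dimension = "overall", category = "all",
                       index = overall,
                       colour = if (is.na(overall)) NA_character_
                                else as.character(colour_of(overall)),
                       n = nrow(fact), stringsAsFactors = FALSE)
  for (dm in c("gender", "region", "weekday", "year", "month")) {
    b <- breakdown(wh, dm)
    if (nrow(b))
      global <- rbind(global, cbind(dimension = dm, b))
  }

  dim <- wh_read(wh, "dim_user")
  hist_rows <- lapply(dim$id_user, function(u) {
    h <- history_report(wh, u)
    if (nrow(h)) cbind(id_user = u, h) else NULL
  })
  history <- do.call(rbind, hist_rows)
  if (is.null(history))
    history <- data.frame(id_user = integer(0), date = character(0),
                          attribute = character(0), old = character(0),
                          new = character(0), stringsAsFactors = FALSE)

  paths <- c(trend = file.path(out_dir, "trend.csv"),
             global = file.path(out_dir, "global.csv"),
             history = file.path(out_dir, "history.csv"))
  write_table_csv(trend, paths["trend"])
  write_table_csv(global, paths["global"])
  write_table_csv(history, paths["history"])
  paths
}
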