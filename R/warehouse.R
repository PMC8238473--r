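# Star-schema warehouse on delimited text tables: a fact table keyed to
# calendar, district and user dimensions, a type-4 slowly-changing user
# dimension with a full history table, watermark-based incremental fact
# loading, and the index-calculation step of the ETL.

wh_schemas <- list(
  fact = c("id_user", "index_date", "bmi", "fam_history", "diabetes",
           "hypertension", "pain_effort", "hypothyroidism",
           "total_cholesterol", "fast_glucose", "age", "smoke_amount",
           "physical_exercise", "systolic_bp", "diastolic_bp",
           "index_value"),
  dim_user = c("id_user", "district", "education", "salary", "gender",
               "active"),
  dim_user_hst = c("id_user", "district", "education", "salary", "gender",
                   "valid_from", "valid_to"),
  dim_calendar = c("date", "year", "month", "day", "weekday"),
  dim_district = c("code", "name", "province", "region", "coastal"),
  watermark = c("source", "value"),
  quarantine = c("id_user", "index_date", "reason")
)

#' ETL configuration: banding and threshold choices
#'
#' Salary is stored in the user dimension as a banded varchar; daily
#' calories map to the four physical-exercise levels. Both mappings are
#' open implementation choices and therefore configurable.
#'
#' @param salary_breaks Ascending interior break points (EUR/month).
#' @param exercise_breaks Ascending interior break points (kcal/day):
#'   defaults give None < 100, Low 100-299, Moderate 300-599, High >= 600.
#' @return A list of class `cwb_etl_config`.
#' @export
etl_config <- function(salary_breaks = c(700, 1200, 2000, 3500),
                       exercise_breaks = c(100, 300, 600)) {
  structure(list(salary_breaks = salary_breaks,
                 exercise_breaks = exercise_breaks),
            class = "cwb_etl_config")
}

salary_band <- function(salary, config = etl_config()) {
  br <- config$salary_breaks
  labels <- c(paste0("<", br[1]),
              paste0(br[-length(br)], "-", br[-1] - 1),
              paste0(">=", br[length(br)]))
  labels[findInterval(salary, br) + 1L]
}

exercise_level <- function(calories, config = etl_config()) {
  c("None", "Low", "Moderate", "High")[
    findInterval(calories, config$exercise_breaks) + 1L]
}

#' Initialize an empty warehouse
#'
#' Creates the five schema tables (fact, user, user history, calendar,
#' district) plus watermark and quarantine bookkeeping as empty CSV files
#' under `location`.
#'
#' @param location Writable directory (created if absent).
#' @param overwrite Re-initialize an existing warehouse (default FALSE:
#'   re-init without overwrite is an error).
#' @return A `cwb_warehouse` handle.
#' @export
init_warehouse <- function(location, overwrite = FALSE) {
  marker <- file.path(location, "fact.csv")
  if (file.exists(marker) && !overwrite)
    stop("warehouse already initialized at ", location,
         " (use overwrite = TRUE)")
  dir.create(location, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(location)) stop("cannot create warehouse at ", location)
  wh <- structure(list(path = location), class = "cwb_warehouse")
  for (tb in names(wh_schemas)) {
    empty <- as.data.frame(stats::setNames(
      replicate(length(wh_schemas[[tb]]), character(0), simplify = FALSE),
      wh_schemas[[tb]]))
    wh_write(wh, tb, empty)
  }
  wh
}

#' Open an existing warehouse directory
#' @param location Directory previously passed to [init_warehouse()].
#' @return A `cwb_warehouse` handle.
#' @export
open_warehouse <- function(location) {
  if (!file.exists(file.path(location, "fact.csv")))
    stop("no warehouse at ", location, "; run init_warehouse() first")
  structure(list(path = location), class = "cwb_warehouse")
}

wh_file <- function(wh, table) file.path(wh$path, paste0(table, ".csv"))

#' Read one warehouse table
#' @param wh A `cwb_warehouse`.
#' @param table Table name (e.g. `"fact"`, `"dim_user_hst"`).
#' @return The table as a data.frame.
#' @export
wh_read <- function(wh, table) {
  stopifnot(table %in% names(wh_schemas))
  df <- read_table_csv(wh_file(wh, table))
  numeric_cols <- list(
    fact = c("id_user", "bmi", "total_cholesterol", "fast_glucose", "age",
             "smoke_amount", "systolic_bp", "diastolic_bp", "index_value"),
    dim_user = "id_user", dim_user_hst = "id_user",
    dim_calendar = c("year", "month", "day")
  )[[table]]
  for (cn in intersect(numeric_cols, names(df)))
    df[[cn]] <- as.numeric(df[[cn]])
  for (cn in intersect(c("id_user", "year", "month", "day"), names(df)))
    if (is.numeric(df[[cn]])) df[[cn]] <- as.integer(df[[cn]])
  df
}

wh_write <- function(wh, table, df) {
  stopifnot(table %in% names(wh_schemas))
  write_table_csv(df[, wh_schemas[[table]], drop = FALSE],
                  wh_file(wh, table))
}

get_watermark <- function(wh, source) {
  w <- wh_read(wh, "watermark")
  v <- w$value[w$source == source]
  if (length(v)) v[1] else NA_character_
}

set_watermark <- function(wh, source, value) {
  w <- wh_read(wh, "watermark")
  old <- w$value[w$source == source]
  if (length(old) && old[1] > value)
    stop("watermark for ", source, " may not move backwards")
  w <- w[w$source != source, , drop = FALSE]
  w <- rbind(w, data.frame(source = source, value = value,
                           stringsAsFactors = FALSE))
  wh_write(wh, "watermark", w)
}

#' Full-load the static dimensions
#'
#' Populates the calendar dimension over a date range and the district
#' dimension from a lookup table. Both are loaded once: a second call is a
#' no-op reporting zero rows.
#'
#' @param wh A `cwb_warehouse`.
#' @param calendar_range Length-2 date vector (inclusive).
#' @param districts District lookup (default [district_fixture()]).
#' @return Named integer vector of newly loaded row counts.
#' @export
load_static_dimensions <- function(wh, calendar_range,
                                   districts = district_fixture()) {
  loaded <- c(dim_calendar = 0L, dim_district = 0L)
  cal <- wh_read(wh, "dim_calendar")
  if (!nrow(cal)) {
    r <- as.Date(calendar_range)
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2])
      stop("calendar_range must be two ordered dates")
    dates <- seq(r[1], r[2], by = "day")
    lt <- as.POSIXlt(dates)
    cal <- data.frame(date = format(dates, "%Y-%m-%d"),
                      year = lt$year + 1900L, month = lt$mon + 1L,
                      day = lt$mday, weekday = weekday_name(dates),
                      stringsAsFactors = FALSE)
    wh_write(wh, "dim_calendar", cal)
    loaded["dim_calendar"] <- nrow(cal)
  }
  dd <- wh_read(wh, "dim_district")
  if (!nrow(dd)) {
    districts <- as.data.frame(districts)
    missing_cols <- setdiff(wh_schemas$dim_district, names(districts))
    if (length(missing_cols))
      stop("district rows lack columns: ",
           paste(missing_cols, collapse = ", "))
    if (anyDuplicated(districts$code))
      stop("district codes must be unique")
    wh_write(wh, "dim_district", districts)
    loaded["dim_district"] <- nrow(districts)
  }
  loaded
}

#' Apply one user snapshot to the SCD type-4 user dimension
#'
#' Change capture by snapshot diffing. A new user is inserted with an open
#' history interval; a changed user closes the previous interval at `at`
#' and opens a new one; an unchanged snapshot is a no-op; a tombstone
#' (`removed = TRUE`) closes the interval and marks the current row
#' inactive. Per user, history intervals stay disjoint and contiguous with
#' exactly one open interval matching the current row.
#'
#' @param wh A `cwb_warehouse`.
#' @param snapshot Named list or one-row data.frame with `id_user`,
#'   `district`, `education_level` (or `education`), `salary` (numeric,
#'   banded on load) and `gender`; or `id_user` plus `removed = TRUE`.
#' @param at Effective date of the snapshot.
#' @param config An [etl_config()] for salary banding.
#' @return A list `(action, changed)` describing what happened.
#' @export
apply_user_snapshot <- function(wh, snapshot, at, config = etl_config()) {
  dim <- wh_read(wh, "dim_user")
  hst <- wh_read(wh, "dim_user_hst")
  res <- scd4_apply(dim, hst, snapshot, at, config)
  wh_write(wh, "dim_user", res$dim)
  wh_write(wh, "dim_user_hst", res$hst)
  res[c("action", "changed")]
}

# Core SCD4 transition on in-memory tables.
scd4_apply <- function(dim, hst, snapshot, at, config = etl_config()) {
  snapshot <- as.list(as.data.frame(snapshot, stringsAsFactors = FALSE))
  at <- format(as.Date(at), "%Y-%m-%d")
  id <- as.integer(snapshot$id_user)
  open_idx <- which(hst$id_user == id & is.na(hst$valid_to))
  if (length(open_idx) && hst$valid_from[open_idx] > at)
    stop("snapshot for user ", id, " predates its open interval")

  if (isTRUE(snapshot$removed)) {
    if (!length(open_idx)) return(list(dim = dim, hst = hst,
                                       action = "none", changed = character(0)))
    hst$valid_to[open_idx] <- at
    dim$active[dim$id_user == id] <- "No"
    return(list(dim = dim, hst = hst, action = "remove",
                changed = character(0)))
  }

  new_row <- data.frame(
    id_user = id,
    district = as.character(snapshot$district),
    education = as.character(snapshot$education_level %||%
                               snapshot$education),
    salary = if (is.numeric(snapshot$salary))
      salary_band(snapshot$salary, config) else as.character(snapshot$salary),
    gender = as.character(snapshot$gender),
    active = "Yes", stringsAsFactors = FALSE
  )
  cur_idx <- which(dim$id_user == id)
  tracked <- c("district", "education", "salary", "gender")
  if (!length(cur_idx)) {
    dim <- rbind(dim, new_row)
    hst <- rbind(hst, cbind(new_row[tracked],
                            data.frame(id_user = id, valid_from = at,
                                       valid_to = NA_character_))[,
                              wh_schemas$dim_user_hst])
    return(list(dim = dim, hst = hst, action = "insert", changed = tracked))
  }
  changed <- tracked[vapply(tracked, function(f)
    !identical(dim[[f]][cur_idx], new_row[[f]]), logical(1))]
  if (!length(changed) && identical(dim$active[cur_idx], "Yes"))
    return(list(dim = dim, hst = hst, action = "none",
                changed = character(0)))
  hst$valid_to[open_idx] <- at
  hst <- rbind(hst, cbind(new_row[tracked],
                          data.frame(id_user = id, valid_from = at,
                                     valid_to = NA_character_))[,
                            wh_schemas$dim_user_hst])
  dim[cur_idx, names(new_row)] <- new_row
  list(dim = dim, hst = hst, action = "update", changed = changed)
}

#' Derive the fact-table fields from a snapshot and a measurement
#'
#' Applies the source-to-target transformations: BMI = weight / height^2
#' (height in metres, supplied in cm), age = full calendar years between
#' date of birth and the clinical analysis date, lifetime smoke amount =
#' 365 x cigarettes/day x smoking years / 1000 (thousands of cigarettes),
#' and the calories-to-physical-exercise banding.
#'
#' @param snapshot Named list/one-row data.frame with the source-1 fields.
#' @param measurement Named list/one-row data.frame with the source-2
#'   fields.
#' @param config An [etl_config()].
#' @return Named list of derived fields: `bmi`, `age`, `smoke_amount`,
#'   `physical_exercise`.
#' @examples
#' derive_fact_fields(
#'   list(weight = 80, height = 180, date_of_birth = "1975-06-01",
#'        clinical_analysis_date = "2019-06-01",
#'        cigarettes_day = 10, smoke_years = 10),
#'   list(calories = 450))
#' @export
derive_fact_fields <- function(snapshot, measurement,
                               config = etl_config()) {
  s <- as.list(as.data.frame(snapshot, stringsAsFactors = FALSE))
  m <- as.list(as.data.frame(measurement, stringsAsFactors = FALSE))
  if (is.null(s$height) || s$height <= 0)
    stop("height must be positive")
  dob <- as.Date(s$date_of_birth)
  cad <- as.Date(s$clinical_analysis_date)
  if (dob >= cad) stop("date of birth must precede the analysis date")
  list(bmi = round(s$weight / (s$height / 100)^2, 2),
       age = full_years_between(dob, cad),
       smoke_amount = 365 * s$cigarettes_day * s$smoke_years / 1000,
       physical_exercise = exercise_level(m$calories, config))
}

# Risk-attribute record assembled for the classifier from the user's
# current snapshot and one measurement.
assemble_risk_record <- function(snap, meas, derived) {
  data.frame(
    age = derived$age, systolic_bp = meas$systolic_bp,
    diastolic_bp = meas$diastolic_bp,
    cholesterol = snap$total_cholesterol,
    fast_glucose = snap$fast_glucose, smoke_years = snap$smoke_years,
    cigarettes_day = snap$cigarettes_day, bmi = derived$bmi,
    family_history = snap$family_history, pain_effort = snap$pain_effort,
    physical_exercise = derived$physical_exercise,
    smoking = ifelse(snap$cigarettes_day > 0, "Yes", "No"),
    hypertension = snap$hypertension, hypothyroid = snap$hypothyroidism,
    gender = snap$gender, stringsAsFactors = FALSE
  )
}

#' Run one incremental ETL pass
#'
#' Populates dimensions before facts: static dimensions (first run only),
#' then the user dimension through SCD4 snapshot diffing, then the fact
#' table. Only measurements dated after the fact watermark (and at or
#' before `at`) are loaded; each new fact's index value is the exponential
#' transform of the selected classifier's disease probability for the
#' user's current attributes plus the measurement. Measurements for
#' unknown users are quarantined and logged while the ETL continues. A
#' rerun with no new data loads zero rows.
#'
#' @param wh A `cwb_warehouse`.
#' @param sources List with data.frames `users` and `measurements` (as
#'   produced by [generate_user_sources()]), optional `districts`, and
#'   optional `calendar_range`.
#' @param model A `cwb_model` (the selected classifier).
#' @param curve A `cwb_index_curve`.
#' @param at Upper date bound of this run (default: today).
#' @param config An [etl_config()].
#' @return A `cwb_etl_report` with per-stage row counts.
#' @export
run_etl <- function(wh, sources, model, curve, at = Sys.Date(),
                    config = etl_config()) {
  stopifnot(inherits(wh, "cwb_warehouse"), inherits(model, "cwb_model"),
            inherits(curve, "cwb_index_curve"))
  at <- as.Date(at)
  users <- sources$users
  meas <- sources$measurements

  cal_range <- sources$calendar_range %||%
    range(as.Date(c(meas$index_date, users$snapshot_date)))
  static <- load_static_dimensions(wh, cal_range,
                                   sources$districts %||% district_fixture())

  # --- user dimension (SCD4, incremental on snapshot_date) ---
  wm_users <- get_watermark(wh, "users")
  snaps <- users[order(users$snapshot_date, users$id_user), , drop = FALSE]
  sel <- as.Date(snaps$snapshot_date) <= at
  if (!is.na(wm_users)) sel <- sel & (snaps$snapshot_date > wm_users)
  snaps <- snaps[sel, , drop = FALSE]
  dim <- wh_read(wh, "dim_user"); hst <- wh_read(wh, "dim_user_hst")
  n_ins <- n_upd <- 0L
  for (i in seq_len(nrow(snaps))) {
    res <- scd4_apply(dim, hst, snaps[i, ], snaps$snapshot_date[i], config)
    dim <- res$dim; hst <- res$hst
    if (res$action == "insert") n_ins <- n_ins + 1L
    if (res$action == "update") n_upd <- n_upd + 1L
  }
  wh_write(wh, "dim_user", dim)
  wh_write(wh, "dim_user_hst", hst)
  if (nrow(snaps))
    set_watermark(wh, "users", max(snaps$snapshot_date))

  # --- fact table (incremental on index_date, index calculation) ---
  wm_facts <- get_watermark(wh, "facts")
  newm <- meas[as.Date(meas$index_date) <= at, , drop = FALSE]
  if (!is.na(wm_facts))
    newm <- newm[newm$index_date > wm_facts, , drop = FALSE]
  newm <- newm[!duplicated(newm[c("id_user", "index_date")]), , drop = FALSE]

  n_quar <- 0L
  n_facts <- 0L
  if (nrow(newm)) {
    known <- newm$id_user %in% dim$id_user[dim$active == "Yes"]
    if (any(!known)) {
      q <- wh_read(wh, "quarantine")
      q <- rbind(q, data.frame(id_user = newm$id_user[!known],
                               index_date = newm$index_date[!known],
                               reason = "unknown_user",
                               stringsAsFactors = FALSE))
      wh_write(wh, "quarantine", q)
      n_quar <- sum(!known)
      newm <- newm[known, , drop = FALSE]
    }
  }
  if (nrow(newm)) {
    # latest source-1 snapshot per user supplies the clinical attributes
    latest <- users[order(users$id_user, users$snapshot_date), , drop = FALSE]
    latest <- latest[!duplicated(latest$id_user, fromLast = TRUE), ,
                     drop = FALSE]
    snap <- latest[match(newm$id_user, latest$id_user), , drop = FALSE]
    derived <- list(
      bmi = round(snap$weight / (snap$height / 100)^2, 2),
      age = full_years_between(snap$date_of_birth,
                               snap$clinical_analysis_date),
      smoke_amount = 365 * snap$cigarettes_day * snap$smoke_years / 1000,
      physical_exercise = exercise_level(newm$calories, config)
    )
    risk <- assemble_risk_record(snap, newm, derived)
    p <- predict_prob(model, risk)
    facts <- data.frame(
      id_user = newm$id_user, index_date = newm$index_date,
      bmi = derived$bmi, fam_history = snap$family_history,
      diabetes = snap$diabetes, hypertension = snap$hypertension,
      pain_effort = snap$pain_effort, hypothyroidism = snap$hypothyroidism,
      total_cholesterol = snap$total_cholesterol,
      fast_glucose = snap$fast_glucose, age = derived$age,
      smoke_amount = derived$smoke_amount,
      physical_exercise = derived$physical_exercise,
      systolic_bp = newm$systolic_bp, diastolic_bp = newm$diastolic_bp,
      index_value = round(index_of(curve, p), 4),
      stringsAsFactors = FALSE
    )
    fact <- wh_read(wh, "fact")
    dupe <- paste(facts$id_user, facts$index_date) %in%
      paste(fact$id_user, fact$index_date)
    facts <- facts[!dupe, , drop = FALSE]
    fact <- rbind(fact, facts)
    wh_write(wh, "fact", fact)
    n_facts <- nrow(facts)
    set_watermark(wh, "facts", max(newm$index_date))
  }

  structure(list(static_loaded = static, users_inserted = n_ins,
                 users_updated = n_upd, facts_loaded = n_facts,
                 quarantined = n_quar, at = format(at, "%Y-%m-%d")),
            class = "cwb_etl_report")
}

#' @export
print.cwb_etl_report <- function(x, ...) {
  cat("ETL run (through ", x$at, "): ", x$facts_loaded, " facts loaded, ",
      x$users_inserted, " users inserted, ", x$users_updated,
      " updated, ", x$quarantined, " measurements quarantined\n", sep = "")
  if (any(x$static_loaded > 0))
    cat("  static dimensions loaded: ",
        paste(names(x$static_loaded), x$static_loaded, sep = " = ",
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.cwb_warehouse <- function(x, ...) {
  cat("cardiowell warehouse at ", x$path, "\n", sep = "")
  for (tb in c("fact", "dim_user", "dim_user_hst", "dim_calendar",
               "dim_district"))
    cat("  ", tb, ": ", nrow(wh_read(x, tb)), " rows\n", sep = "")
  invisible(x)
}
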