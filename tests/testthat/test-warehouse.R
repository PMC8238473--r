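test_that("initialization creates the five schema tables exactly once", {
  loc <- withr::local_tempdir()
  wh <- init_warehouse(loc)
  for (tb in c("fact", "dim_user", "dim_user_hst", "dim_calendar",
               "dim_district"))
    expect_identical(nrow(wh_read(wh, tb)), 0L)
  expect_error(init_warehouse(loc), "already initialized")
  wh2 <- init_warehouse(loc, overwrite = TRUE)
  expect_identical(nrow(wh_read(wh2, "fact")), 0L)
  expect_error(open_warehouse(withr::local_tempdir()), "init_warehouse")
})

test_that("static dimensions full-load once and only once", {
  wh <- temp_warehouse()
  loaded <- load_static_dimensions(wh, c("2019-01-01", "2019-12-31"))
  expect_identical(unname(loaded["dim_calendar"]), 365L)
  expect_identical(unname(loaded["dim_district"]), 18L)
  again <- load_static_dimensions(wh, c("2019-01-01", "2019-12-31"))
  expect_identical(unname(again), c(0L, 0L))
  cal <- wh_read(wh, "dim_calendar")
  expect_identical(cal$weekday[cal$date == "2019-10-20"], "Sunday")
  expect_identical(sum(cal$month == 2), 28L)
  expect_error(load_static_dimensions(temp_warehouse(),
                                      c("2019-12-31", "2019-01-01")),
               "ordered")
})

test_that("a residence change closes one interval and opens another", {
  wh <- temp_warehouse()
  apply_user_snapshot(wh, snapshot_of(4, district = "LSB"), "2019-01-15")
  res <- apply_user_snapshot(wh, snapshot_of(4, district = "VCT"),
                             "2019-10-20")
  expect_identical(res$action, "update")
  expect_identical(res$changed, "district")
  h <- wh_read(wh, "dim_user_hst")
  closed <- h[!is.na(h$valid_to), ]
  open <- h[is.na(h$valid_to), ]
  expect_identical(nrow(closed), 1L)
  expect_identical(nrow(open), 1L)
  expect_identical(closed$district, "LSB")
  expect_identical(closed$valid_to, "2019-10-20")
  expect_identical(open$district, "VCT")
  expect_identical(open$valid_from, "2019-10-20")
  expect_identical(wh_read(wh, "dim_user")$district, "VCT")
})

test_that("re-applying an identical snapshot is a no-op", {
  wh <- temp_warehouse()
  apply_user_snapshot(wh, snapshot_of(1), "2019-01-01")
  before <- wh_read(wh, "dim_user_hst")
  res <- apply_user_snapshot(wh, snapshot_of(1), "2019-02-01")
  expect_identical(res$action, "none")
  expect_identical(wh_read(wh, "dim_user_hst"), before)
})

test_that("successive changes keep intervals disjoint and contiguous", {
  wh <- temp_warehouse()
  apply_user_snapshot(wh, snapshot_of(9, salary = 800), "2019-01-01")
  new_salaries <- c(1500, 2500, 4000) # each crosses a band edge
  for (i in 1:3)
    apply_user_snapshot(wh, snapshot_of(9, salary = new_salaries[i]),
                        paste0("2019-0", i + 1, "-01"))
  h <- wh_read(wh, "dim_user_hst")
  h <- h[order(h$valid_from), ]
  expect_identical(nrow(h), 4L)
  expect_identical(sum(is.na(h$valid_to)), 1L)
  expect_identical(h$valid_to[1:3], h$valid_from[2:4]) # contiguous
  cur <- wh_read(wh, "dim_user")
  expect_identical(cur$salary, h$salary[4])
  expect_error(apply_user_snapshot(wh, snapshot_of(9), "2018-12-01"),
               "predates")
})

test_that("tombstones close the interval and deactivate the user", {
  wh <- temp_warehouse()
  apply_user_snapshot(wh, snapshot_of(2), "2019-01-01")
  res <- apply_user_snapshot(wh, list(id_user = 2, removed = TRUE),
                             "2019-06-01")
  expect_identical(res$action, "remove")
  expect_identical(sum(is.na(wh_read(wh, "dim_user_hst")$valid_to)), 0L)
  expect_identical(wh_read(wh, "dim_user")$active, "No")
})

test_that("derived fact fields follow the source-to-target formulas", {
  snap <- list(weight = 80, height = 180, date_of_birth = "1975-06-01",
               clinical_analysis_date = "2019-05-31",
               cigarettes_day = 10, smoke_years = 10)
  d <- derive_fact_fields(snap, list(calories = 450))
  expect_equal(d$bmi, 24.69, tolerance = 1e-3)
  expect_identical(d$smoke_amount, 36.5) # 365 x 10 x 10 / 1000
  expect_identical(d$age, 43L)
  snap$clinical_analysis_date <- "2019-06-01"
  expect_identical(derive_fact_fields(snap, list(calories = 450))$age, 44L)
  snap$cigarettes_day <- 0
  expect_identical(derive_fact_fields(snap, list(calories = 450))$smoke_amount, 0)
  expect_error(derive_fact_fields(c(snap, height = NULL)[names(snap) != "height"],
                                  list(calories = 1)), "height")
  snap$height <- 0
  expect_error(derive_fact_fields(snap, list(calories = 1)), "height")
  snap$height <- 180
  snap$date_of_birth <- "2020-01-01"
  expect_error(derive_fact_fields(snap, list(calories = 1)), "precede")
})

test_that("calories map onto the exercise bands at the documented edges", {
  d <- function(cal) derive_fact_fields(
    list(weight = 70, height = 170, date_of_birth = "1980-01-01",
         clinical_analysis_date = "2019-01-01", cigarettes_day = 0,
         smoke_years = 0),
    list(calories = cal))$physical_exercise
  expect_identical(vapply(c(99, 100, 299, 300, 599, 600), d, character(1)),
                   c("None", "Low", "Low", "Moderate", "Moderate", "High"))
})

make_loaded_warehouse <- function(n_users = 10, n_days = 30, seed = 7,
                                  change_rate = 0.5) {
  coh <- clean_cohort(400, seed = seed)
  model <- fit_classifier(technique_specs("I", "NB")[[1]], coh, seed = seed)
  curve <- fit_index_curve()
  src <- generate_user_sources(n_users, n_days, seed = seed,
                               change_rate = change_rate)
  wh <- init_warehouse(withr::local_tempdir(.local_envir = parent.frame()))
  list(wh = wh, src = src, model = model, curve = curve,
       report = run_etl(wh, src, model, curve, at = as.Date("2019-12-31")))
}

test_that("the ETL loads dimensions before facts and counts add up", {
  env <- make_loaded_warehouse(10, 30)
  expect_identical(env$report$facts_loaded, 300L)
  expect_identical(env$report$users_inserted, 10L)
  fact <- wh_read(env$wh, "fact")
  expect_identical(nrow(fact), 300L)
  expect_false(anyDuplicated(fact[c("id_user", "index_date")]) > 0)
  expect_true(all(fact$index_value >= -5 & fact$index_value <= 5))
  # referential integrity: every fact key resolves in its dimension
  expect_true(all(fact$id_user %in% wh_read(env$wh, "dim_user")$id_user))
  expect_true(all(fact$index_date %in% wh_read(env$wh, "dim_calendar")$date))
  dd <- wh_read(env$wh, "dim_district")
  expect_true(all(wh_read(env$wh, "dim_user")$district %in% dd$code))
})

test_that("a rerun with no new data is a no-op and watermarks only advance", {
  env <- make_loaded_warehouse(5, 10)
  wm1 <- cardiowell:::get_watermark(env$wh, "facts")
  again <- run_etl(env$wh, env$src, env$model, env$curve,
                   at = as.Date("2019-12-31"))
  expect_identical(again$facts_loaded, 0L)
  expect_identical(again$users_inserted + again$users_updated, 0L)
  expect_identical(nrow(wh_read(env$wh, "fact")), 50L)
  expect_identical(cardiowell:::get_watermark(env$wh, "facts"), wm1)
  expect_error(cardiowell:::set_watermark(env$wh, "facts", "2000-01-01"),
               "backwards")
})

test_that("only measurements past the watermark are loaded incrementally", {
  env <- make_loaded_warehouse(5, 10)
  m <- env$src$measurements
  extra <- m[m$index_date == max(m$index_date), ][1:5, ]
  extra$index_date <- "2019-03-01" # after watermark 2019-01-10
  src2 <- env$src
  src2$measurements <- rbind(m, extra)
  rep2 <- run_etl(env$wh, src2, env$model, env$curve,
                  at = as.Date("2019-12-31"))
  expect_identical(rep2$facts_loaded, 5L)
})

test_that("measurements for unknown users are quarantined, not fatal", {
  env <- make_loaded_warehouse(3, 5)
  src2 <- env$src
  src2$measurements <- rbind(
    src2$measurements,
    data.frame(id_user = 999L, index_date = "2019-06-01", calories = 200L,
               systolic_bp = 120L, diastolic_bp = 80L))
  rep2 <- run_etl(env$wh, src2, env$model, env$curve,
                  at = as.Date("2019-12-31"))
  expect_identical(rep2$quarantined, 1L)
  expect_identical(rep2$facts_loaded, 0L)
  q <- wh_read(env$wh, "quarantine")
  expect_identical(q$id_user, 999L)
  expect_identical(q$reason, "unknown_user")
})

test_that("SCD4 history satisfies the partition property for every user", {
  env <- make_loaded_warehouse(12, 25, seed = 11, change_rate = 1)
  hst <- wh_read(env$wh, "dim_user_hst")
  dim <- wh_read(env$wh, "dim_user")
  for (u in unique(hst$id_user)) {
    h <- hst[hst$id_user == u, ]
    h <- h[order(h$valid_from), ]
    expect_identical(sum(is.na(h$valid_to)), 1L) # exactly one open interval
    expect_true(is.na(h$valid_to[nrow(h)]))
    if (nrow(h) > 1)
      expect_identical(h$valid_to[-nrow(h)], h$valid_from[-1])
    open <- h[nrow(h), ]
    cur <- dim[dim$id_user == u, ]
    expect_identical(open[, c("district", "education", "salary", "gender")],
                     cur[, c("district", "education", "salary", "gender")],
                     ignore_attr = TRUE)
  }
})

test_that("replaying history snapshots reconstructs the current dimension", {
  env <- make_loaded_warehouse(8, 20, seed = 13, change_rate = 1)
  hst <- wh_read(env$wh, "dim_user_hst")
  replay_wh <- init_warehouse(withr::local_tempdir())
  hst <- hst[order(hst$valid_from, hst$id_user), ]
  for (i in seq_len(nrow(hst))) {
    r <- hst[i, ]
    apply_user_snapshot(replay_wh,
                        list(id_user = r$id_user, district = r$district,
                             education_level = r$education,
                             salary = r$salary, gender = r$gender),
                        r$valid_from)
  }
  orig <- wh_read(env$wh, "dim_user")
  rebuilt <- wh_read(replay_wh, "dim_user")
  orig <- orig[order(orig$id_user), ]; rebuilt <- rebuilt[order(rebuilt$id_user), ]
  expect_identical(rebuilt, orig, ignore_attr = TRUE)
})
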