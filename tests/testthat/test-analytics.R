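test_that("weighted index matches closed forms on tiny series", {
  d0 <- as.Date("2019-03-01")
  one <- data.frame(date = d0, index_value = 2.0)
  expect_identical(weighted_index(one, d0), 2.0)
  two <- data.frame(date = c(d0, d0 + 10), index_value = c(2, 4))
  expect_equal(weighted_index(two, d0 + 10), 4.0)
  expect_equal(weighted_index(two, d0 + 5), 3.0)
  flat <- data.frame(date = d0 + 0:19, index_value = rep(3.68, 20))
  expect_equal(weighted_index(flat, d0 + 19), 3.68)
  expect_equal(weighted_index(flat, d0 + 7), 3.68)
})

test_that("caller-side windowing and preconditions behave as declared", {
  d0 <- as.Date("2019-01-01")
  h <- data.frame(date = d0 + c(0, 5, 10, 50), index_value = c(1, 2, 3, -5))
  # monitoring callers window the series themselves: no look-ahead
  windowed <- h[h$date <= d0 + 10, ]
  expect_equal(weighted_index(windowed, d0 + 10), 3.0)
  expect_error(weighted_index(h[0, ], d0), "at least one")
  expect_error(weighted_index(h, d0 - 1), "precedes")
  dup <- data.frame(date = c(d0, d0), index_value = c(1, 2))
  expect_error(weighted_index(dup, d0), "unique")
})

test_that("weighted index equals an independent OLS oracle up to length 6", {
  d0 <- as.Date("2019-06-01")
  set.seed(17)
  for (len in 2:6) {
    for (rep in 1:10) {
      t_off <- sort(sample(0:30, len))
      h <- data.frame(date = d0 + t_off,
                      index_value = round(stats::runif(len, -5, 5), 3))
      tq <- max(t_off) + sample(0:5, 1)
      fit <- stats::lm(index_value ~ t, data = transform(h, t = t_off))
      oracle <- stats::predict(fit, data.frame(t = tq))
      oracle <- min(5, max(-5, unname(oracle)))
      expect_equal(weighted_index(h, d0 + tq), oracle, tolerance = 1e-9)
    }
  }
})

test_that("extrapolated trends are clamped to the index scale", {
  d0 <- as.Date("2019-01-01")
  steep <- data.frame(date = d0 + c(0, 1, 2), index_value = c(0, 2.5, 5))
  expect_identical(weighted_index(steep, d0 + 10), 5)
})

# Builds a warehouse with directly planted facts (bypassing the model) so
# analytic aggregates can be checked against hand-computed values.
planted_warehouse <- function(facts, users = NULL) {
  wh <- init_warehouse(withr::local_tempdir(.local_envir = parent.frame()))
  load_static_dimensions(wh, range(facts$index_date))
  if (is.null(users))
    users <- data.frame(id_user = unique(facts$id_user), district = "LSB",
                        gender = "Female")
  for (i in seq_len(nrow(users)))
    apply_user_snapshot(wh, list(id_user = users$id_user[i],
                                 district = users$district[i],
                                 education_level = "Basic", salary = 1000,
                                 gender = users$gender[i]),
                        min(facts$index_date))
  tmpl <- data.frame(
    bmi = 25, fam_history = "No", diabetes = "No", hypertension = "No",
    pain_effort = "No", hypothyroidism = "No", total_cholesterol = 170,
    fast_glucose = 100, age = 50, smoke_amount = 0,
    physical_exercise = "Moderate", systolic_bp = 120, diastolic_bp = 80)
  full <- cbind(facts, tmpl[rep(1, nrow(facts)), , drop = FALSE])
  cardiowell:::wh_write(wh, "fact", full)
  wh
}

test_that("the global index is the plain mean of stored index values", {
  facts <- data.frame(id_user = 1L, index_date = paste0("2019-01-0", 1:3),
                      index_value = c(-1, -2, -3))
  wh <- planted_warehouse(facts)
  expect_identical(global_index(wh), -2)
  expect_identical(global_index(wh, "gender", "Female"), -2)
  expect_identical(global_index(wh, "gender", "Male"), NA_real_) # no data
  expect_error(global_index(wh, "shoe_size"), "unknown")
  single <- planted_warehouse(data.frame(id_user = 1L,
                                         index_date = "2019-01-01",
                                         index_value = 3.2))
  expect_identical(global_index(single), 3.2)
})

test_that("an engineered overall mean is recovered exactly", {
  set.seed(23)
  v <- round(stats::runif(40, -5, 5), 4)
  facts <- data.frame(id_user = rep(1:4, each = 10),
                      index_date = rep(format(as.Date("2019-01-01") + 0:9,
                                              "%Y-%m-%d"), 4),
                      index_value = v)
  wh <- planted_warehouse(facts)
  expect_equal(global_index(wh), sum(v) / length(v), tolerance = 1e-12)
})

test_that("breakdowns conserve the global mean and recover planted effects", {
  # two genders with planted means -1 and +1, equal counts
  facts <- data.frame(id_user = rep(1:2, each = 4),
                      index_date = rep(format(as.Date("2019-01-07") + 0:3,
                                              "%Y-%m-%d"), 2),
                      index_value = c(rep(-1, 4), rep(1, 4)))
  users <- data.frame(id_user = 1:2, district = c("LSB", "PRT"),
                      gender = c("Female", "Male"))
  wh <- planted_warehouse(facts, users)
  b <- breakdown(wh, "gender")
  expect_setequal(b$category, c("Female", "Male"))
  expect_equal(sum(b$index * b$n) / sum(b$n), global_index(wh),
               tolerance = 1e-9)
  expect_equal(global_index(wh), 0)
  expect_identical(b$colour, as.character(colour_of(b$index)))

  # planted Monday deficit: Mondays carry the minimal mean
  dates <- format(as.Date("2019-01-07") + 0:13, "%Y-%m-%d") # two weeks
  wd <- weekdays(as.Date(dates))
  facts2 <- data.frame(id_user = 1L, index_date = dates,
                       index_value = ifelse(wd == "Monday", -4, 1))
  wh2 <- planted_warehouse(facts2)
  b2 <- breakdown(wh2, "weekday")
  expect_identical(b2$category[which.min(b2$index)], "Monday")
  # count-weighted conservation across weekday slices
  expect_equal(sum(b2$index * b2$n) / sum(b2$n), global_index(wh2),
               tolerance = 1e-9)

  only_one <- breakdown(wh2, "gender")
  expect_identical(nrow(only_one), 1L)
})

test_that("history reports list tracked changes chronologically", {
  wh <- temp_warehouse()
  apply_user_snapshot(wh, snapshot_of(4, district = "LSB"), "2019-01-01")
  apply_user_snapshot(wh, snapshot_of(4, district = "VCT"), "2019-10-20")
  h <- history_report(wh, 4)
  expect_identical(nrow(h), 1L)
  expect_identical(h$date, "2019-10-20")
  expect_identical(h$attribute, "residence")
  expect_identical(h$old, "LSB")
  expect_identical(h$new, "VCT")

  apply_user_snapshot(wh, snapshot_of(5), "2019-01-01")
  expect_identical(nrow(history_report(wh, 5)), 0L)
  expect_error(history_report(wh, 999), "unknown user")

  apply_user_snapshot(wh, snapshot_of(5, education = "Master"), "2019-03-01")
  apply_user_snapshot(wh, snapshot_of(5, education = "Master",
                                      salary = 2500), "2019-05-01")
  apply_user_snapshot(wh, snapshot_of(5, education = "Master", salary = 2500,
                                      district = "FAR"), "2019-07-01")
  h5 <- history_report(wh, 5)
  expect_identical(nrow(h5), 3L)
  expect_identical(h5$date, c("2019-03-01", "2019-05-01", "2019-07-01"))
  expect_identical(h5$attribute, c("education", "salary", "residence"))
})

test_that("report export writes consistent, header-complete files", {
  facts <- data.frame(id_user = rep(1:2, times = c(3, 2)),
                      index_date = c(paste0("2019-01-0", 1:3),
                                     paste0("2019-01-0", 1:2)),
                      index_value = c(3, 3.5, 4, -3, -4))
  wh <- planted_warehouse(facts)
  out <- withr::local_tempdir()
  paths <- export_report(wh, out)
  expect_true(all(file.exists(paths)))

  trend <- utils::read.csv(paths["trend"])
  expect_identical(names(trend), c("id_user", "date", "index_value",
                                   "weighted_index", "colour"))
  expect_identical(nrow(trend[trend$id_user == 1, ]), 3L) # per-user fact count
  expect_identical(nrow(trend[trend$id_user == 2, ]), 2L)
  expect_identical(trend$colour,
                   as.character(colour_of(trend$weighted_index)))

  glob <- utils::read.csv(paths["global"])
  overall <- glob[glob$dimension == "overall", ]
  expect_equal(overall$index, global_index(wh), tolerance = 1e-6)
  expect_identical(overall$colour, as.character(colour_of(overall$index)))

  # empty warehouse still yields valid header-only files
  empty <- init_warehouse(withr::local_tempdir())
  paths0 <- export_report(empty, withr::local_tempdir())
  t0 <- utils::read.csv(paths0["trend"])
  expect_identical(nrow(t0), 0L)
  expect_identical(names(t0), names(trend))
})
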