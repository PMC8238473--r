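# Synthetic data generation: the classified training cohort and the three
# operational sources (user snapshots, daily measurements, district lookup).

#' Generate a synthetic classified risk-factor cohort
#'
#' Draws `n` records whose marginals emulate the calibration: truncated
#' normals for the numeric attributes (location-adjusted so the truncated
#' mean matches the calibration mean), category frequencies for the nominal
#' ones, missing-completely-at-random smoking status, an entirely missing
#' diabetes column, and a contamination fraction of rows carrying one gross
#' out-of-range extreme (negative blood pressures, absurd BMI) mimicking the
#' raw data the cleansing stage must catch.
#'
#' The Disease label is driven by a logit-linear latent model in the
#' standardized pre-contamination attributes, so classifiers have real
#' signal to learn. The intercept is calibrated by root-finding so the mean
#' latent probability equals the calibration prevalence. With
#' `exact_balance = TRUE` labels are assigned by ranking latent
#' probabilities and cutting at exactly `round(n * prevalence)` Disease
#' rows (ties broken by row index), making the printed class counts an
#' exact target.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param calibration A [cohort_calibration()] object.
#' @param exact_balance Logical; exact rank-cut class allocation instead of
#'   Bernoulli draws.
#' @return A data.frame with the 17 risk attributes plus `class`
#'   (factor, levels `Disease`, `No disease`).
#' @examples
#' cohort <- generate_cohort(200, seed = 1)
#' table(cohort$class)
#' @export
generate_cohort <- function(n, seed, calibration = cohort_calibration(),
                            exact_balance = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  validate_calibration(calibration)
  cal <- calibration

  with_seed(seed, {
    num <- cal$numeric
    clean <- matrix(NA_real_, n, nrow(num),
                    dimnames = list(NULL, num$attribute))
    for (i in seq_len(nrow(num))) {
      mu <- truncnorm_location(num$mean[i], num$sd[i],
                               num$min_clean[i], num$max_clean[i])
      x <- rtruncnorm(n, mu, num$sd[i], num$min_clean[i], num$max_clean[i])
      clean[, i] <- round(x, num$digits[i])
    }

    nom <- lapply(names(cal$nominal), function(attr) {
      counts <- cal$nominal[[attr]]
      v <- sample(names(counts), n, replace = TRUE, prob = counts / sum(counts))
      miss_rate <- unname(cal$missing[attr])
      if (!is.na(miss_rate) && miss_rate > 0)
        v[stats::runif(n) < miss_rate] <- NA_character_
      v
    })
    names(nom) <- names(cal$nominal)

    # Latent disease model on pre-contamination values.
    eta <- rep(0, n)
    bnum <- cal$beta$numeric
    for (a in names(bnum)) {
      i <- match(a, num$attribute)
      eta <- eta + bnum[[a]] * (clean[, a] - num$mean[i]) / num$sd[i]
    }
    for (a in names(cal$nominal)) {
      eff <- cal$beta[[a]][nom[[a]]]
      eff[is.na(eff)] <- 0
      eta <- eta + eff
    }
    prevalence <- cal$class_counts[["Disease"]] / sum(cal$class_counts)
    b0 <- stats::uniroot(function(b) mean(stats::plogis(eta + b)) - prevalence,
                         c(-30, 30), tol = 1e-10)$root
    p <- stats::plogis(eta + b0)
    if (exact_balance) {
      k <- round(n * prevalence)
      ord <- order(-p, seq_len(n))
      label <- rep("No disease", n)
      label[ord[seq_len(k)]] <- "Disease"
    } else {
      label <- ifelse(stats::runif(n) < p, "Disease", "No disease")
    }

    # Contamination: a fraction of rows gets one attribute replaced by an
    # extreme drawn from the printed out-of-range tails.
    contaminable <- which(num$min_extreme < num$min_clean |
                            num$max_extreme > num$max_clean)
    if (cal$contamination > 0 && length(contaminable)) {
      rows <- which(stats::runif(n) < cal$contamination)
      if (length(rows)) {
        cols <- sample(contaminable, length(rows), replace = TRUE)
        for (j in unique(cols)) {
          r <- rows[cols == j]
          lo_ok <- num$min_extreme[j] < num$min_clean[j]
          hi_ok <- num$max_extreme[j] > num$max_clean[j]
          side <- if (lo_ok && hi_ok) stats::runif(length(r)) < 0.5
                  else rep(lo_ok, length(r))
          v <- numeric(length(r))
          v[side] <- stats::runif(sum(side), num$min_extreme[j],
                                  num$min_clean[j])
          v[!side] <- stats::runif(sum(!side), num$max_clean[j],
                                   num$max_extreme[j])
          clean[r, j] <- round(v, num$digits[j])
        }
      }
    }

    dr <- cal$record_date_range
    record_date <- dr[1] + sample.int(as.integer(dr[2] - dr[1]) + 1L, n,
                                      replace = TRUE) - 1L

    out <- data.frame(clean, stringsAsFactors = FALSE)
    for (a in names(nom)) out[[a]] <- nom[[a]]
    out$record_date <- record_date
    out$diabetes <- NA_character_
    out$class <- factor(label, levels = c("Disease", "No disease"))
    out[, c(cohort_attributes(), "class")]
  })
}

#' Generate the two synthesized operational sources
#'
#' Source 1 holds slowly-varying personal/clinical user records; source 2
#' holds daily measurements (calories spent, blood pressures). A
#' `change_rate` fraction of users receives at least one later snapshot with
#' a modified district, education level and/or salary, exercising the
#' type-4 slowly-changing user dimension downstream.
#'
#' @param n_users,n_days Positive integers.
#' @param seed Integer seed.
#' @param change_rate Fraction of users in `[0, 1]` with a later changed
#'   snapshot (default 0.2).
#' @param start_date First measurement date (default `"2019-01-01"`).
#' @return A list with data.frames `users` (one or more dated snapshots per
#'   user) and `measurements` (one row per user and day).
#' @examples
#' src <- generate_user_sources(5, 10, seed = 1)
#' nrow(src$measurements)
#' @export
generate_user_sources <- function(n_users, n_days, seed, change_rate = 0.2,
                                  start_date = "2019-01-01") {
  if (!is.numeric(n_users) || n_users < 1) stop("n_users must be positive")
  if (!is.numeric(n_days) || n_days < 1) stop("n_days must be positive")
  if (change_rate < 0 || change_rate > 1) stop("change_rate must be in [0, 1]")
  n_users <- as.integer(n_users); n_days <- as.integer(n_days)
  start_date <- as.Date(start_date)
  districts <- district_fixture()
  educations <- c("Basic", "Secondary", "Bachelor", "Master", "Doctorate")

  with_seed(seed, {
    id <- seq_len(n_users)
    age <- round(rtruncnorm(n_users, 52.8, 6.8, 25, 90))
    analysis_date <- start_date - sample.int(60, n_users, replace = TRUE)
    dob <- analysis_date - round(age * 365.25) -
      sample.int(300, n_users, replace = TRUE)
    smoke_years <- ifelse(stats::runif(n_users) < 0.3,
                          sample.int(40, n_users, replace = TRUE), 0L)
    users <- data.frame(
      id_user = id,
      snapshot_date = format(start_date, "%Y-%m-%d"),
      district = sample(districts$code, n_users, replace = TRUE),
      education_level = sample(educations, n_users, replace = TRUE,
                               prob = c(0.3, 0.35, 0.2, 0.1, 0.05)),
      salary = as.integer(round(exp(stats::rnorm(n_users, log(1300), 0.4)))),
      gender = sample(c("Male", "Female"), n_users, replace = TRUE,
                      prob = c(28326, 36674)),
      weight = as.integer(round(rtruncnorm(n_users, 78, 14, 45, 140))),
      height = as.integer(round(rtruncnorm(n_users, 168, 9, 145, 200))),
      family_history = sample(c("Yes", "No"), n_users, TRUE, c(8459, 56541)),
      diabetes = sample(c("Yes", "No"), n_users, TRUE, c(0.1, 0.9)),
      hypertension = sample(c("Yes", "No"), n_users, TRUE, c(25225, 39775)),
      pain_effort = sample(c("Yes", "No"), n_users, TRUE, c(8620, 56380)),
      hypothyroidism = sample(c("Yes", "No"), n_users, TRUE, c(13501, 51499)),
      total_cholesterol = as.integer(round(rtruncnorm(n_users, 170.1, 52.5,
                                                      80, 500))),
      fast_glucose = as.integer(round(rtruncnorm(n_users, 119.6, 56.4,
                                                 40, 500))),
      clinical_analysis_date = format(analysis_date, "%Y-%m-%d"),
      date_of_birth = format(dob, "%Y-%m-%d"),
      cigarettes_day = ifelse(smoke_years > 0,
                              sample.int(40, n_users, replace = TRUE), 0L),
      smoke_years = smoke_years,
      stringsAsFactors = FALSE
    )

    n_changed <- round(change_rate * n_users)
    if (n_changed > 0 && n_days > 1) {
      changed <- sample(id, n_changed)
      extra <- users[match(changed, users$id_user), ]
      when <- start_date + sample.int(n_days - 1L, n_changed, replace = TRUE)
      extra$snapshot_date <- format(when, "%Y-%m-%d")
      for (i in seq_len(n_changed)) {
        what <- sample(c("district", "education_level", "salary"),
                       sample.int(3, 1))
        if ("district" %in% what)
          extra$district[i] <- sample(setdiff(districts$code,
                                              extra$district[i]), 1)
        if ("education_level" %in% what)
          extra$education_level[i] <- sample(setdiff(educations,
                                                     extra$education_level[i]), 1)
        if ("salary" %in% what)
          extra$salary[i] <- as.integer(round(extra$salary[i] *
                                                stats::runif(1, 1.1, 1.6)))
      }
      users <- rbind(users, extra)
      users <- users[order(users$id_user, users$snapshot_date), ]
      rownames(users) <- NULL
    } else if (n_changed > 0 && n_days == 1) {
      # degenerate one-day span: changes would collide with the initial
      # snapshot date, so none are emitted
      n_changed <- 0L
    }

    base_sbp <- round(rtruncnorm(n_users, 128, 14, 95, 185))
    base_dbp <- round(pmin(rtruncnorm(n_users, 82, 9, 55, 110),
                           base_sbp - 20))
    days <- rep(seq_len(n_days) - 1L, times = n_users)
    uid <- rep(id, each = n_days)
    m <- length(uid)
    measurements <- data.frame(
      id_user = uid,
      index_date = format(start_date + days, "%Y-%m-%d"),
      calories = as.integer(round(pmin(exp(stats::rnorm(m, log(350), 0.8)),
                                       4000))),
      systolic_bp = as.integer(base_sbp[uid] +
                                 round(stats::rnorm(m, 0, 7))),
      diastolic_bp = as.integer(base_dbp[uid] +
                                  round(stats::rnorm(m, 0, 5))),
      stringsAsFactors = FALSE
    )
    list(users = users, measurements = measurements)
  })
}

#' District lookup table for Portugal
#'
#' The packaged 18-district lookup (source 3): code, name, traditional
#' province, statistical region and coastal flag. Unlike the two user
#' sources this table is based on real administrative geography.
#'
#' @return A data.frame with 18 rows and unique `code` keys.
#' @examples
#' subset(district_fixture(), code %in% c("LSB", "VCT"))
#' @export
district_fixture <- function() {
  path <- system.file("extdata", "districts.csv", package = "cardiowell")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "districts.csv")
  read_table_csv(path, colClasses = "character")
}

#' Write cohort or source tables as CSV
#'
#' CSV writers for the generated tables: header row mandatory, empty string
#' encodes missing, dates ISO-8601.
#'
#' @param x A data.frame produced by [generate_cohort()] or
#'   [generate_user_sources()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(x, path) write_table_csv(x, path)

#' Read a cohort CSV written by [write_cohort_csv()]
#' @param path File path.
#' @return A cohort data.frame with `class` as a factor.
#' @export
read_cohort_csv <- function(path) {
  df <- read_table_csv(path)
  if (!"diabetes" %in% names(df)) df$diabetes <- NA_character_
  df$diabetes <- as.character(df$diabetes)
  if ("record_date" %in% names(df)) df$record_date <- as.Date(df$record_date)
  if ("class" %in% names(df))
    df$class <- factor(df$class, levels = c("Disease", "No disease"))
  df
}
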