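# Calibration of the synthetic cohort generator.
#
# The defaults emulate the marginal statistics of the 65,000-record
# development dataset of the index system: per-attribute means/spreads and
# printed extremes for the eight numeric risk factors, category counts for
# the seven nominal ones, the smoking missingness rate, the all-missing
# diabetes column, and the near-balanced Disease / No disease split.

#' Default calibration for the synthetic risk-factor cohort
#'
#' Returns the target marginal statistics, missingness pattern, class
#' balance, outlier contamination and latent disease-model coefficients used
#' by [generate_cohort()]. Defaults reproduce the development cohort the
#' index system was built on: 65,000 records, 17 risk attributes, 32,509
#' Disease labels.
#'
#' Numeric attributes are described by a target mean, a clean-data standard
#' deviation, the physiological range used for clean generation, and the
#' gross extremes (e.g. a systolic pressure of -150 or 16020) that outlier
#' contamination can inject. For systolic and diastolic pressure the printed
#' whole-data standard deviations are dominated by those gross outliers, so
#' the clean spreads default to plausible physiological values (15 and
#' 12 mmHg).
#'
#' The class label comes from a logit-linear latent model in the
#' standardized risk attributes. Coefficient signs follow established
#' cardiovascular epidemiology: risk increases with age, blood pressure,
#' cholesterol, glucose, smoking exposure, BMI, family history, effort pain
#' and hypertension, and decreases with physical exercise level.
#'
#' @param effect Effect-size preset for the latent disease model:
#'   `"moderate"` (default, classifier performance in the 0.7-0.8 accuracy
#'   range) or `"strong"` (sharply separable cohort, used for end-to-end
#'   sanity checks).
#' @param contamination Fraction of rows in `[0, 1]` that receive one
#'   out-of-range extreme value (default 0.02).
#' @return An object of class `cwb_calibration`.
#' @examples
#' cal <- cohort_calibration()
#' cal$class_counts
#' @export
cohort_calibration <- function(effect = c("moderate", "strong"),
                               contamination = 0.02) {
  effect <- match.arg(effect)
  numeric <- data.frame(
    attribute = c("age", "systolic_bp", "diastolic_bp", "cholesterol",
                  "fast_glucose", "smoke_years", "cigarettes_day", "bmi"),
    mean = c(52.8, 128.9, 96.9, 170.1, 119.6, 5.4, 7.1, 27.6),
    sd = c(6.8, 15, 12, 52.5, 56.4, 12.0, 14.6, 6.1),
    min_clean = c(18, 60, 30, 80, 40, 0, 0, 10),
    max_clean = c(100, 250, 150, 500, 500, 80, 80, 70),
    min_extreme = c(29, -150, -70, 100, 80, 0, 0, 3.5),
    max_extreme = c(64, 16020, 11000, 320, 400, 50, 50, 298.7),
    digits = c(0, 0, 0, 0, 0, 0, 0, 1),
    stringsAsFactors = FALSE
  )
  nominal <- list(
    family_history = c(Yes = 8459, No = 56541),
    pain_effort = c(Yes = 8620, No = 56380),
    physical_exercise = c(None = 6352, Low = 6413,
                          Moderate = 26054, High = 26181),
    smoking = c(Yes = 6651, No = 23393),
    hypertension = c(Yes = 25225, No = 39775),
    hypothyroid = c(Yes = 13501, No = 51499),
    gender = c(Male = 28326, Female = 36674)
  )
  scale <- switch(effect, moderate = 1, strong = 3)
  beta <- list(
    numeric = c(age = 0.40, systolic_bp = 0.60, diastolic_bp = 0.30,
                cholesterol = 0.40, fast_glucose = 0.35, smoke_years = 0.25,
                cigarettes_day = 0.25, bmi = 0.35) * scale,
    family_history = c(Yes = 0.5, No = 0) * scale,
    pain_effort = c(Yes = 0.4, No = 0) * scale,
    physical_exercise = c(None = 0, Low = -0.15,
                          Moderate = -0.35, High = -0.5) * scale,
    smoking = c(Yes = 0.4, No = 0) * scale, # missing contributes 0
    hypertension = c(Yes = 0.6, No = 0) * scale,
    hypothyroid = c(Yes = 0.1, No = 0) * scale,
    gender = c(Male = 0.2, Female = 0) * scale
  )
  cal <- structure(list(
    reference_n = 65000L,
    numeric = numeric,
    nominal = nominal,
    missing = c(smoking = 34956 / 65000, diabetes = 1),
    class_counts = c(Disease = 32509L, `No disease` = 32491L),
    contamination = contamination,
    beta = beta,
    effect = effect,
    record_date_range = as.Date(c("2019-01-01", "2019-12-31"))
  ), class = "cwb_calibration")
  validate_calibration(cal)
  cal
}

#' @noRd
validate_calibration <- function(cal) {
  stopifnot(inherits(cal, "cwb_calibration"))
  num <- cal$numeric
  if (any(num$sd < 0)) stop("calibration: sd must be non-negative")
  if (any(num$min_clean > num$mean | num$mean > num$max_clean))
    stop("calibration: each numeric mean must lie inside its clean range")
  n <- cal$reference_n
  for (attr in names(cal$nominal)) {
    tot <- sum(cal$nominal[[attr]])
    miss <- round(unname(cal$missing[attr] %||% 0) * n)
    if (is.na(miss)) miss <- 0
    if (tot + miss != n)
      stop(sprintf("calibration: %s frequencies (%d) + missing do not sum to %d",
                   attr, tot, n))
  }
  if (sum(cal$class_counts) != n)
    stop("calibration: class counts must sum to the cohort size")
  if (cal$contamination < 0 || cal$contamination > 1)
    stop("calibration: contamination rate must lie in [0, 1]")
  invisible(cal)
}

#' @export
print.cwb_calibration <- function(x, ...) {
  cat("Synthetic cohort calibration (", x$reference_n, " reference records)\n",
      sep = "")
  cat("  effect preset: ", x$effect,
      ", contamination rate: ", x$contamination, "\n", sep = "")
  cat("  class balance: ", paste(names(x$class_counts), x$class_counts,
                                 sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Column order of a raw cohort table: 17 risk attributes + class.
cohort_attributes <- function() {
  c("age", "systolic_bp", "diastolic_bp", "cholesterol", "fast_glucose",
    "smoke_years", "cigarettes_day", "bmi",
    "family_history", "pain_effort", "physical_exercise", "smoking",
    "hypertension", "hypothyroid", "gender", "record_date", "diabetes")
}

# Attributes usable as classifier features (record_date is bookkeeping,
# diabetes is generated entirely missing and dropped by cleansing).
predictive_attributes <- function() {
  setdiff(cohort_attributes(), c("record_date", "diabetes"))
}
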