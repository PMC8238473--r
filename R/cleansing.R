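# Pre-processing of the raw cohort: sort, drop superseded duplicates,
# reject records violating physiological or structural rules, drop unusable
# columns, and log every rejection with a reason code.

#' Default cleansing rules for the risk-factor cohort
#'
#' Numeric range predicates (wide enough to keep all plausible clean mass,
#' tight enough to reject the gross extremes present in raw data, such as
#' negative blood pressures or a BMI of 298.7), the structural requirement
#' systolic > diastolic, the policy for superseded duplicates, and the flag
#' dropping columns that are entirely missing (the diabetes column in raw
#' cohorts).
#'
#' Missing values are not treated as incoherent: a record with unknown
#' smoking status is kept.
#'
#' @param ranges Named list of `c(lo, hi)` numeric ranges, replacing or
#'   extending the defaults.
#' @param require_sbp_above_dbp Enforce systolic > diastolic (default TRUE).
#' @param drop_all_missing_columns Drop columns with no observed value
#'   (default TRUE).
#' @param dedupe Keep only the latest `record_date` per duplicated subject
#'   key (default TRUE); the subject key is every attribute except
#'   `record_date`.
#' @return An object of class `cwb_cleansing_rules`.
#' @export
cleansing_rules <- function(ranges = list(),
                            require_sbp_above_dbp = TRUE,
                            drop_all_missing_columns = TRUE,
                            dedupe = TRUE) {
  default <- list(
    systolic_bp = c(60, 250), diastolic_bp = c(30, 150),
    bmi = c(10, 70), cholesterol = c(80, 500), fast_glucose = c(40, 500),
    age = c(18, 100), smoke_years = c(0, 80), cigarettes_day = c(0, 80)
  )
  for (a in names(ranges)) {
    r <- ranges[[a]]
    if (!is.numeric(r) || length(r) != 2L || r[1] > r[2])
      stop("each range must be a non-empty numeric interval c(lo, hi)")
    default[[a]] <- r
  }
  structure(list(ranges = default,
                 require_sbp_above_dbp = isTRUE(require_sbp_above_dbp),
                 drop_all_missing_columns = isTRUE(drop_all_missing_columns),
                 dedupe = isTRUE(dedupe)),
            class = "cwb_cleansing_rules")
}

#' Validate one record against the cleansing rules
#'
#' Pure predicate: returns the violation codes for a single record, an
#' empty character vector when the record passes every rule. Missing values
#' never trigger a range violation.
#'
#' @param record A one-row data.frame (or named list) with the cohort schema.
#' @param rules A [cleansing_rules()] object.
#' @return Character vector of violation codes such as
#'   `"bmi_out_of_range"` or `"systolic_not_above_diastolic"`.
#' @examples
#' r <- generate_cohort(1, seed = 1, cohort_calibration(contamination = 0))
#' validate_record(r, cleansing_rules())
#' @export
validate_record <- function(record, rules = cleansing_rules()) {
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(record) != 1L) stop("validate_record expects exactly one record")
  unknown <- setdiff(names(rules$ranges), names(record))
  if (length(unknown))
    stop("rules name attributes absent from the record: ",
         paste(unknown, collapse = ", "))
  codes <- character(0)
  for (a in names(rules$ranges)) {
    v <- record[[a]]
    r <- rules$ranges[[a]]
    if (!is.na(v) && (v < r[1] || v > r[2]))
      codes <- c(codes, paste0(a, "_out_of_range"))
  }
  if (rules$require_sbp_above_dbp) {
    s <- record[["systolic_bp"]]; d <- record[["diastolic_bp"]]
    if (!is.na(s) && !is.na(d) && s <= d)
      codes <- c(codes, "systolic_not_above_diastolic")
  }
  codes
}

#' Cleanse a raw cohort table
#'
#' Sorts by record date, removes superseded duplicates (same subject key,
#' older record date), rejects records violating any rule predicate, drops
#' all-missing columns, and reports every rejection with its reason codes.
#' Idempotent: cleansing already-clean data changes nothing.
#'
#' @param records Raw cohort data.frame (17-attribute schema + `class`).
#' @param rules A [cleansing_rules()] object.
#' @return A list of class `cwb_cleansing_result`: `clean` (the kept
#'   table) and `report` (a `cwb_cleansing_report` with input/kept counts,
#'   per-record rejection reasons and dropped columns).
#' @examples
#' raw <- generate_cohort(100, seed = 1)
#' res <- cleanse(raw)
#' res$report
#' @export
cleanse <- function(records, rules = cleansing_rules()) {
  stopifnot(is.data.frame(records))
  known <- names(records)
  unknown <- setdiff(names(rules$ranges), known)
  if (nrow(records) > 0 && length(unknown))
    stop("rules name attributes absent from the table: ",
         paste(unknown, collapse = ", "))

  n <- nrow(records)
  reject_reason <- vector("list", n)

  # Superseded duplicates: keep latest record_date per subject key.
  if (rules$dedupe && n > 0 && "record_date" %in% known) {
    keycols <- setdiff(known, "record_date")
    key <- do.call(paste, c(records[keycols], sep = "\r"))
    rd <- as.Date(records$record_date)
    ord <- order(key, rd, seq_len(n)) # latest (then last-seen) wins
    last_of_key <- !duplicated(key[ord], fromLast = TRUE)
    superseded <- ord[!last_of_key]
    for (i in superseded) reject_reason[[i]] <- "outdated_superseded"
  }

  # Vectorized rule predicates (same semantics as validate_record).
  if (n > 0) {
    for (a in names(rules$ranges)) {
      v <- records[[a]]
      r <- rules$ranges[[a]]
      bad <- which(!is.na(v) & (v < r[1] | v > r[2]))
      code <- paste0(a, "_out_of_range")
      for (i in bad) reject_reason[[i]] <- c(reject_reason[[i]], code)
    }
    if (rules$require_sbp_above_dbp &&
        all(c("systolic_bp", "diastolic_bp") %in% known)) {
      s <- records$systolic_bp; d <- records$diastolic_bp
      bad <- which(!is.na(s) & !is.na(d) & s <= d)
      for (i in bad)
        reject_reason[[i]] <- c(reject_reason[[i]],
                                "systolic_not_above_diastolic")
    }
  }

  rejected_idx <- which(lengths(reject_reason) > 0)
  kept <- records[setdiff(seq_len(n), rejected_idx), , drop = FALSE]

  dropped_cols <- character(0)
  if (rules$drop_all_missing_columns && nrow(kept) > 0) {
    all_missing <- vapply(kept, function(col) all(is.na(col)), logical(1))
    if ("class" %in% names(all_missing))
      all_missing[["class"]] <- FALSE # the label is never dropped
    dropped_cols <- names(kept)[all_missing]
    kept <- kept[, !all_missing, drop = FALSE]
  } else if (rules$drop_all_missing_columns && n == 0 &&
             "diabetes" %in% known) {
    dropped_cols <- "diabetes"
    kept <- kept[, setdiff(known, "diabetes"), drop = FALSE]
  }
  if ("record_date" %in% names(kept)) {
    ord <- order(as.Date(kept$record_date), seq_len(nrow(kept)))
    kept <- kept[ord, , drop = FALSE]
  }
  rownames(kept) <- NULL

  rejected <- data.frame(
    row = rejected_idx,
    reasons = vapply(reject_reason[rejected_idx], paste,
                     character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  report <- structure(list(input_n = n, kept_n = nrow(kept),
                           rejected = rejected,
                           dropped_columns = dropped_cols),
                      class = "cwb_cleansing_report")
  structure(list(clean = kept, report = report),
            class = "cwb_cleansing_result")
}

#' @export
print.cwb_cleansing_report <- function(x, ...) {
  cat("Cleansing report: ", x$kept_n, " of ", x$input_n, " records kept, ",
      nrow(x$rejected), " rejected\n", sep = "")
  if (length(x$dropped_columns))
    cat("  dropped all-missing columns: ",
        paste(x$dropped_columns, collapse = ", "), "\n", sep = "")
  if (nrow(x$rejected)) {
    tab <- sort(table(unlist(strsplit(x$rejected$reasons, ";"))),
                decreasing = TRUE)
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Write a cleansing rejection log as CSV
#' @param report A `cwb_cleansing_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rejection_log <- function(report, path) {
  write_table_csv(report$rejected, path)
}
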