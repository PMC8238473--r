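# Shared fixtures, all built in code at test time.

# Clean cohort: no contamination, so every value passes the default rules.
clean_cohort <- function(n, seed = 1, effect = "moderate",
                         exact_balance = FALSE) {
  coh <- generate_cohort(n, seed = seed,
                         cohort_calibration(effect = effect,
                                            contamination = 0),
                         exact_balance = exact_balance)
  coh <- cleanse(coh)$clean # drops all-missing diabetes, structural culls
  coh
}

# Toy cohort whose class is fully determined by one numeric threshold.
separable_cohort <- function(n = 100, seed = 1) {
  set.seed(seed)
  x <- c(stats::runif(n / 2, 0, 0.4), stats::runif(n / 2, 0.6, 1))
  data.frame(
    marker = x,
    filler = stats::rnorm(n),
    class = factor(ifelse(x > 0.5, "Disease", "No disease"),
                   levels = c("Disease", "No disease"))
  )
}

# Minimal user snapshot for SCD4 tests.
snapshot_of <- function(id, district = "LSB", education = "Secondary",
                        salary = 1000, gender = "Female") {
  list(id_user = id, district = district, education_level = education,
       salary = salary, gender = gender)
}

temp_warehouse <- function() init_warehouse(withr::local_tempdir(
  .local_envir = parent.frame()))
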