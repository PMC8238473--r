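test_that("the composite score is the exact midpoint of its metrics", {
  expect_equal(score(0.700, 0.753), 0.7265)
  expect_equal(score(0.703, 0.748), 0.7255)
  expect_identical(score(1, 1), 1)
  expect_identical(score(0.7, 0.753), score(0.753, 0.7)) # symmetric
  expect_error(score(1.2, 0.5), "\\[0, 1\\]")
  expect_error(score(0.5, -0.1), "\\[0, 1\\]")
  set.seed(1)
  s <- stats::runif(50); a <- stats::runif(50)
  v <- score(s, a)
  expect_true(all(v >= pmin(s, a) & v <= pmax(s, a)))
})

test_that("confusion-matrix metrics follow their definitions", {
  m <- cardiowell:::confusion_metrics(tp = 70, fn = 30, tn = 80, fp = 20)
  expect_equal(m$sensitivity, 0.70)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$score, 0.725)
})

test_that("ranking the benchmark metric pairs reproduces the known order", {
  ranked <- rank_models(reference_training_metrics())
  expect_identical(ranked$algorithm,
                   c("MLP", "RF", "J48", "ASJ48", "ASKNN",
                     "ASMLP", "ASRF", "KNN", "NB", "ASNB"))
  expect_equal(ranked$score[1:3], c(0.7265, 0.7255, 0.7225))
})

test_that("ranking is a permutation with the declared tie rules", {
  one <- rank_models(data.frame(algorithm = "X", sensitivity = 0.5,
                                accuracy = 0.5))
  expect_identical(one$algorithm, "X")
  ties <- data.frame(algorithm = c("A", "B"),
                     sensitivity = c(0.6, 0.7),
                     accuracy = c(0.8, 0.7))
  expect_identical(rank_models(ties)$algorithm, c("B", "A")) # equal scores
  df <- reference_training_metrics()
  expect_setequal(rank_models(df)$algorithm, df$algorithm)
  expect_error(rank_models(df[0, ]), "no results")
})

test_that("feature selection keeps signal and drops noise and duplicates", {
  set.seed(5)
  n <- 5000
  latent <- stats::rnorm(n)
  cohort <- data.frame(
    driver = latent + stats::rnorm(n, 0, 0.3),
    duplicate = NA_real_,
    noise = stats::runif(n),
    class = factor(ifelse(latent > 0, "Disease", "No disease"),
                   levels = c("Disease", "No disease"))
  )
  cohort$duplicate <- cohort$driver # identical column
  feats <- select_features(cohort, features = c("driver", "duplicate",
                                                "noise"))
  ranking <- attr(feats, "ranking")
  expect_identical(ranking[1], "driver") # perfect predictor ranks first
  expect_false("noise" %in% feats)
  expect_lte(sum(c("driver", "duplicate") %in% feats), 2L)
  expect_true("driver" %in% feats)
  expect_false(all(c("driver", "duplicate", "noise") %in% feats))
})

test_that("feature selection yields a strict non-empty subset on cohorts", {
  coh <- clean_cohort(800, seed = 3)
  candidates <- intersect(cardiowell:::predictive_attributes(), names(coh))
  feats <- select_features(coh)
  expect_gt(length(feats), 0)
  expect_lt(length(feats), length(candidates))
  expect_true(all(feats %in% candidates))
  expect_error(select_features(coh[coh$class == "Disease", ]), "both classes")
})

test_that("cross-validation scores a separable cohort perfectly", {
  toy <- separable_cohort(100)
  spec <- technique_specs("I", "KNN")[[1]]
  ev <- cross_validate(toy, spec, k = 5, seed = 1,
                       features = c("marker", "filler"))
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$score, 1)
})

test_that("label permutation drives accuracy to chance", {
  coh <- clean_cohort(2000, seed = 1)
  set.seed(99)
  coh$class <- coh$class[sample(nrow(coh))] # permuted labels
  ev <- cross_validate(coh, technique_specs("I", "NB")[[1]], k = 10, seed = 1)
  expect_lt(abs(ev$accuracy - 0.5), 0.05)
})

test_that("fold confusions pool to the reported aggregate", {
  coh <- clean_cohort(600, seed = 2)
  ev <- cross_validate(coh, technique_specs("I", "NB")[[1]], k = 6, seed = 3)
  pooled <- Reduce(`+`, ev$fold_confusions)
  expect_identical(unname(pooled), unname(ev$confusion))
  expect_equal(ev$sensitivity,
               ev$confusion[["tp"]] / (ev$confusion[["tp"]] + ev$confusion[["fn"]]))
  expect_equal(ev$score, score(ev$sensitivity, ev$accuracy))
  expect_equal(sum(ev$confusion), nrow(coh))
})

test_that("cross-validation preconditions are enforced", {
  coh <- clean_cohort(30, seed = 4)
  spec <- technique_specs("I", "NB")[[1]]
  expect_error(cross_validate(coh, spec, k = 1), "at least 2")
  expect_error(cross_validate(coh[1:5, ], spec, k = 10))
  single <- coh[coh$class == coh$class[1], ]
  expect_error(cross_validate(single, spec, k = 2), "both classes")
})

test_that("every family fits and predicts calibrated probabilities", {
  coh <- clean_cohort(400, seed = 6)
  for (fam in c("J48", "RF", "NB", "KNN", "MLP")) {
    spec <- technique_specs("I", fam)[[1]]
    model <- fit_classifier(spec, coh, seed = 2)
    p <- predict_prob(model, coh)
    expect_true(all(p >= 0 & p <= 1), label = fam)
    expect_gt(stats::sd(p), 0)
    acc <- mean((p >= 0.5) == (coh$class == "Disease"))
    expect_gt(acc, 0.55) # better than chance on its own training data
  }
})

test_that("a memorizing model scores its own training data perfectly", {
  toy <- separable_cohort(60)
  spec1 <- structure(list(name = "KNN1", base = "KNN", family = "knn",
                          scenario = "I", params = list(k = 1L)),
                     class = "cwb_technique")
  model <- fit_classifier(spec1, toy, features = c("marker", "filler"))
  ev <- holdout_evaluate(model, toy)
  expect_equal(ev$accuracy, 1)
  expect_error(holdout_evaluate(model, toy[, "class", drop = FALSE]),
               "lacks model features")
})

test_that("holdout drift validation compares against a reference", {
  toy <- separable_cohort(200)
  spec <- technique_specs("I", "KNN")[[1]]
  train <- toy[seq(1, 200, by = 2), ] # interleave to keep both classes
  test <- toy[seq(2, 200, by = 2), ]
  model <- fit_classifier(spec, train, features = c("marker", "filler"))
  ref <- list(sensitivity = 1, accuracy = 1)
  ev <- holdout_evaluate(model, test, reference = ref)
  expect_true(attr(ev, "valid"))
  expect_true(all(attr(ev, "drift") <= 0.05))
})

test_that("select_best with injected metrics writes the winner atomically", {
  path <- withr::local_tempfile(fileext = ".txt")
  sel <- select_best(metrics = reference_training_metrics(),
                     name_file = path)
  expect_identical(sel$best_name, "MLP")
  expect_identical(readLines(path), "MLP")
  sel2 <- select_best(metrics = reference_training_metrics(),
                      name_file = path) # rerun overwrites cleanly
  expect_identical(readLines(path), "MLP")
  one <- select_best(metrics = data.frame(algorithm = "NB",
                                          sensitivity = 0.6,
                                          accuracy = 0.6))
  expect_identical(one$best_name, "NB")
  expect_error(select_best(), "cohort or injected metrics")
})

test_that("select_best trains both scenarios deterministically", {
  coh <- clean_cohort(300, seed = 7)
  a <- select_best(coh, families = c("J48", "NB"), seed = 5, k = 3)
  expect_identical(nrow(a$ranking), 4L) # 2 families x 2 scenarios
  expect_setequal(a$ranking$algorithm, c("J48", "NB", "ASJ48", "ASNB"))
  expect_s3_class(a$model, "cwb_model")
  # scenario II features are a strict subset of scenario I
  feats_I <- intersect(cardiowell:::predictive_attributes(), names(coh))
  expect_lt(length(a$features_II), length(feats_I))
  b <- select_best(coh, families = c("J48", "NB"), seed = 5, k = 3)
  expect_identical(a$ranking, b$ranking)
})
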