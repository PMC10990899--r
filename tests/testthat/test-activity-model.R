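test_that("metric summary matches brute-force pair counting on random instances", {
  set.seed(31)
  for (rep in 1:10) {
    truth <- sample(1:4, 60, replace = TRUE)
    pred <- ifelse(runif(60) < 0.7, truth, sample(1:4, 60, replace = TRUE))
    cm <- trainload:::confusion_counts(truth, pred)
    # brute force over (truth, prediction) pairs
    bf <- matrix(0L, 4, 4)
    for (i in seq_along(truth)) bf[truth[i], pred[i]] <- bf[truth[i], pred[i]] + 1L
    expect_equal(unname(cm), bf)

    s <- suppressWarnings(summarize_metrics(cm))
    expect_equal(s$accuracy, mean(truth == pred))
    for (cl in 1:4) {
      p_bf <- if (sum(pred == cl) > 0) sum(truth == cl & pred == cl) / sum(pred == cl) else 0
      r_bf <- if (sum(truth == cl) > 0) sum(truth == cl & pred == cl) / sum(truth == cl) else 0
      expect_equal(s$per_class$precision[cl], p_bf)
      expect_equal(s$per_class$recall[cl], r_bf)
    }
    expect_equal(rowSums(s$confusion), unname(table(factor(truth, levels = 1:4))),
                 ignore_attr = TRUE)
  }
})

test_that("F1 reproduces the published per-class values and its identities", {
  expect_equal(round(f1_score(0.9545, 0.8750), 4), 0.9130)
  expect_equal(round(f1_score(0.9375, 0.9677), 4), 0.9524)
  expect_equal(round(f1_score(0.9091, 0.9375), 4), 0.9231)
  # harmonic mean lies between precision and recall; equals both when equal
  set.seed(5)
  p <- runif(50); r <- runif(50)
  f <- f1_score(p, r)
  expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
  expect_equal(f1_score(0.8, 0.8), 0.8)
  expect_equal(f1_score(0, 0), 0)
})

test_that("perfect confusion matrices give perfect metrics", {
  s <- summarize_metrics(diag(c(10, 10, 10, 10)))
  expect_equal(s$accuracy, 1)
  expect_true(all(s$per_class$precision == 1))
  expect_true(all(s$per_class$f1 == 1))
  expect_error(summarize_metrics(matrix(0, 4, 4)), "all zero")
  expect_error(summarize_metrics(matrix(-1, 4, 4)), "non-negative")
})

test_that("training is deterministic and separable data are memorised", {
  ft <- session_features(seed = 2, n_sets = 3, noise_sd = 0)
  m1 <- train_activity_model(ft, seed = 9, n_trees = 100)
  m2 <- train_activity_model(ft, seed = 9, n_trees = 100)
  probe <- session_features(seed = 4, n_sets = 2, noise_sd = 0.05)
  expect_identical(predict_activity(m1, probe), predict_activity(m2, probe))
  expect_equal(predict_activity(m1, ft), ft$label)  # training rows re-predicted
  expect_identical(predict_activity(m1, ft[0, , drop = FALSE]), integer(0))

  one_class <- ft[ft$label == 1, , drop = FALSE]
  expect_error(train_activity_model(one_class), "single class")
})

test_that("prediction rejects schema mismatches by name", {
  ft <- session_features(seed = 2, n_sets = 2)
  m <- train_activity_model(ft, seed = 1, n_trees = 50)
  bad <- ft
  names(bad)[1] <- "bogus_feature"
  expect_error(predict_activity(m, bad), "bogus_feature")
})

test_that("repeated hold-out evaluation reaches perfect accuracy on separable data", {
  ft <- session_features(seed = 6, n_sets = 16, noise_sd = 0)
  rep10 <- evaluate_holdout(ft, seed = 3, repeats = 10, n_trees = 100)
  expect_equal(rep10$protocol, "holdout_7_3_x10")
  expect_length(rep10$repeats, 10)
  expect_gte(rep10$accuracy, 0.99)
  expect_equal(rep10$accuracy, sum(diag(rep10$confusion)) / sum(rep10$confusion))
  # pooled test-set size: 10 repeats x the stratified 30% complement
  per_class <- table(ft$label)
  expect_equal(sum(rep10$confusion),
               10L * sum(per_class - vapply(per_class, function(n)
                 max(1L, round(n * 0.7)), numeric(1))))
})

test_that("growing-database evaluation yields one report per database", {
  base <- session_spec(seed = 13, n_sets = 3)
  cohort <- make_cohort(3, base)
  fts <- lapply(cohort, function(s) {
    extract_features(segment(s$left, s$right, s$labels))
  })
  reports <- evaluate_growing_db(fts, seed = 1, n_trees = 100)
  expect_length(reports, 2L)
  expect_true(all(vapply(reports, `[[`, character(1), "protocol") == "growing_db"))
  expect_equal(vapply(reports, `[[`, integer(1), "k_train"), 1:2)
  expect_true(all(vapply(reports, `[[`, numeric(1), "accuracy") > 0.8))

  # two identical-distribution subjects, separable data -> perfect database 1
  twin <- make_cohort(2, session_spec(seed = 17, n_sets = 3, noise_sd = 0),
                      variation = list())
  fts2 <- lapply(twin, function(s)
    extract_features(segment(s$left, s$right, s$labels)))
  r2 <- evaluate_growing_db(fts2, seed = 1, n_trees = 100)
  expect_equal(r2[[1]]$accuracy, 1)

  bad <- fts
  names(bad[[2]])[1] <- "other"
  expect_error(evaluate_growing_db(bad), "mismatching schemas")
})

test_that("accuracy degrades toward chance as class separation vanishes", {
  # same signature for every activity: labels carry no signal
  flat <- default_signatures()
  for (a in names(flat)) flat[[a]] <- flat$grip
  accs <- vapply(1:4, function(seed) {
    ft <- session_features(seed = seed, n_sets = 6, noise_sd = 0.1,
                           signature_params = flat)
    suppressWarnings(
      evaluate_holdout(ft, seed = seed, repeats = 2, n_trees = 60)$accuracy)
  }, numeric(1))
  expect_lt(mean(accs), 0.45)  # far below the separable regime, near 1/4
})
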