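# Predictor training, calibrated scoring, fold machinery, nested CV

test_that("a separable toy set is fit perfectly by the linear SVM", {
  toy <- separable_toy()
  # brute-force oracle: some threshold on f1 separates the classes
  thr <- seq(0, 1, by = 0.01)
  best <- max(vapply(thr, function(t) {
    mean((toy$f1 > t) == (toy$label == "aggregating"))
  }, numeric(1)))
  expect_equal(best, 1)
  m <- train_propensity(toy, c("f1", "f2"), method = "svm", cost = 1,
                        seed = 1)
  sc <- predict(m, toy)
  expect_equal(
    confusion_counts(sc, toy$label)$fn + confusion_counts(sc, toy$label)$fp,
    0
  )
})

test_that("training refuses single-class labels and missing features", {
  toy <- separable_toy()
  one <- dplyr::filter(toy, label == "aggregating")
  expect_error(train_propensity(one, c("f1", "f2"), "svm"), "both classes")
  expect_error(train_propensity(toy, c("f1", "nope"), "svm"), "absent")
  m <- train_propensity(toy, c("f1", "f2"), method = "rf", seed = 1)
  expect_error(predict(m, toy["f1"]), "missing feature")
})

test_that("propensities are calibrated to the unit interval", {
  fx <- small_fixture()
  for (method in c("svm", "rf")) {
    m <- train_propensity(fx$encoded, feature_names(fx$encoded),
                          method = method, cost = 1, seed = 3)
    sc <- predict(m, fx$encoded)
    expect_true(all(sc >= 0 & sc <= 1))
  }
})

test_that("random-forest scores are tree-vote fractions", {
  fx <- small_fixture()
  m <- train_propensity(fx$encoded, informative_scales(fx$scales),
                        method = "rf", ntree = 500, seed = 3)
  sc <- predict(m, fx$encoded)
  votes <- sc * 500
  expect_true(all(abs(votes - round(votes)) < 1e-8))
  # clearly separated extremes reach the unanimous endpoints
  expect_gt(max(sc), 0.98)
  expect_lt(min(sc), 0.02)
})

test_that("training and prediction are deterministic under a fixed seed", {
  fx <- small_fixture()
  feats <- informative_scales(fx$scales)
  for (method in c("svm", "rf")) {
    m1 <- train_propensity(fx$encoded, feats, method = method, seed = 11)
    m2 <- train_propensity(fx$encoded, feats, method = method, seed = 11)
    expect_identical(predict(m1, fx$encoded), predict(m2, fx$encoded))
  }
})

test_that("tidy and glance expose weights, importances, and fit summary", {
  fx <- small_fixture()
  feats <- informative_scales(fx$scales)
  ms <- train_propensity(fx$encoded, feats, method = "svm", seed = 2)
  expect_equal(tidy(ms)$term, feats)
  expect_equal(tidy(ms)$weight_sq, tidy(ms)$weight^2)
  mr <- train_propensity(fx$encoded, feats, method = "rf", seed = 2)
  expect_true(all(tidy(mr)$importance >= 0))
  expect_equal(glance(ms)$n_features, 2L)
  expect_equal(glance(mr)$method, "rf")
})

test_that("k-fold splits are near-equal, disjoint, exhaustive, seeded", {
  f <- kfold_splits(354, 10, seed = 3)
  sizes <- lengths(f$test)
  expect_equal(as.integer(sort(table(sizes), decreasing = TRUE)), c(6L, 4L))
  expect_equal(sort(unique(sizes)), c(35, 36))
  all_test <- sort(unname(unlist(f$test)))
  expect_equal(all_test, 1:354) # disjoint union of the index set
  for (i in 1:10) {
    expect_length(intersect(f$train[[i]], f$test[[i]]), 0)
  }
  expect_identical(f$test, kfold_splits(354, 10, seed = 3)$test)
  expect_false(identical(f$test, kfold_splits(354, 10, seed = 4)$test))
  expect_error(kfold_splits(5, 6), "exceed")
})

test_that("LOPO makes one fold per protein plus a pooled de novo fold", {
  pep <- tibble::tibble(
    sequence = "ACDEF",
    protein_group = c("P1", "P1", "P2", "P3", "de_novo", "de_novo")
  )
  f <- lopo_splits(pep)
  expect_equal(nrow(f), 4)
  for (i in seq_len(nrow(f))) {
    expect_length(
      intersect(pep$protein_group[f$train[[i]]],
                pep$protein_group[f$test[[i]]]),
      0
    )
  }
  expect_equal(sort(unlist(f$test)), 1:6)
})

test_that("nested CV recovers a strong planted signal and is deterministic", {
  fx <- small_fixture()
  feats <- informative_scales(fx$scales)
  cv1 <- nested_cv(fx$encoded, feats, "svm", k_outer = 5, k_inner = 5,
                   seed = 5)
  expect_gt(cv1$metrics$accuracy, 0.85)
  expect_gt(cv1$auc, 0.9)
  cv2 <- nested_cv(fx$encoded, feats, "svm", k_outer = 5, k_inner = 5,
                   seed = 5)
  expect_identical(cv1$scores, cv2$scores)
  # pooled counts cover every sample exactly once
  expect_equal(sum(unlist(cv1$counts)), nrow(fx$encoded))
  g <- glance(cv1)
  expect_equal(g$scheme, "kfold")
  expect_equal(nrow(tidy(cv1)), 5)
})

test_that("model archives round-trip and refuse foreign formats", {
  m <- small_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  fx <- small_fixture()
  expect_identical(predict(back, fx$encoded), predict(m, fx$encoded))
  saveRDS(list(format_version = 99L, model = m), path)
  expect_error(load_model(path), "format version")
})
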