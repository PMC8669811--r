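test_that("the forest interpolates a linearly separable training set", {
  f <- separable_features(seed = 4)
  model <- train_rf(f, rf_config(seed = 2))
  pred <- predict(model, f)
  expect_equal(pred$label, f$label)
  expect_equal(confusion_metrics(f$label, pred$label)$acc, 1)
})

test_that("training is deterministic given data and seed", {
  f <- separable_features(seed = 6)
  probe <- separable_features(seed = 60)
  m1 <- train_rf(f, rf_config(seed = 9))
  m2 <- train_rf(f, rf_config(seed = 9))
  expect_identical(predict(m1, probe), predict(m2, probe))
})

test_that("single-class or NA training data is rejected", {
  f <- separable_features(seed = 1)
  one <- f[f$label == 1, ]
  expect_error(train_rf(one, rf_config()), "single class")
  f$sep[3] <- NA
  expect_error(train_rf(f, rf_config()), "NA")
})

test_that("prediction rejects mismatched or permuted feature columns", {
  f <- separable_features(seed = 2)
  model <- train_rf(f, rf_config())
  permuted <- f[, c("sample_id", "label", "noise1", "sep", "noise2")]
  expect_error(predict(model, permuted), "noise1")
  expect_error(predict(model, f[, c("sample_id", "label", "sep")]), "expected")
})

test_that("mtry rules reproduce the classical defaults", {
  expect_equal(rf_config()$n_trees, 100L)
  cfg <- rf_config(mtry = "log2")
  expect_error(rf_config(n_trees = 0), "n_trees")
  expect_error(rf_config(mtry = 0), "mtry")
  # floor(log2(820)) + 1 = 10; floor(sqrt(820)) = 28
  d <- 820
  expect_equal(floor(log2(d)) + 1, 10)
  f <- separable_features(n = 10, seed = 3)
  m <- train_rf(f, rf_config(n_trees = 5, mtry = 100))  # capped at d
  expect_s3_class(m, "aip_rf")
})

test_that("stratified folds partition the samples and balance classes", {
  labels <- rep(c(0L, 1L), c(120, 47))
  folds <- make_folds(labels, folds = 5, seed = 3)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 167)
  per_fold <- table(folds, labels)
  expect_true(all(abs(per_fold[, "1"] - 47 / 5) <= 1))
  expect_true(all(abs(per_fold[, "0"] - 120 / 5) <= 1))
})

test_that("every fold receives a positive even under heavy imbalance", {
  labels <- rep(c(1L, 0L), c(3, 200))
  folds <- make_folds(labels, folds = 2, seed = 1)
  expect_true(all(table(folds[labels == 1]) >= 1))
  expect_error(make_folds(labels, folds = 5), "smallest class")
  expect_error(make_folds(labels, folds = 1), "2 folds")
})

test_that("cross-validation pools out-of-fold scores over all samples", {
  f <- separable_features(n = 40, seed = 12)
  cv <- cross_validate(f, rf_config(seed = 5), folds = 5, cv_seed = 7)
  expect_equal(cv$pooled$tp + cv$pooled$tn + cv$pooled$fp + cv$pooled$fn, 40)
  expect_equal(cv$pooled$auc, 1)  # perfectly separating feature
  expect_length(cv$per_fold, 5)
  expect_equal(nrow(tidy(cv)), 5)
  expect_equal(glance(cv)$auc, 1)
})

test_that("cross-validation is reproducible and seed-sensitive", {
  f <- separable_features(n = 30, seed = 14)
  cv1 <- cross_validate(f, rf_config(seed = 5), cv_seed = 7)
  cv2 <- cross_validate(f, rf_config(seed = 5), cv_seed = 7)
  expect_identical(glance(cv1$pooled), glance(cv2$pooled))
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  cv3 <- cross_validate(f, rf_config(seed = 5), cv_seed = 8)
  expect_false(identical(cv1$fold_assignment, cv3$fold_assignment))
})

test_that("label-independent features give chance-level pooled AUC", {
  withr::with_seed(31, {
    f <- dplyr::bind_cols(
      tibble::tibble(sample_id = paste0("S", 1:100),
                     label = rep(c(0L, 1L), 50)),
      tibble::as_tibble(matrix(rnorm(100 * 8), nrow = 100,
                               dimnames = list(NULL, paste0("f", 1:8))))
    )
  })
  cv <- cross_validate(f, rf_config(seed = 2), cv_seed = 3)
  expect_gt(cv$pooled$auc, 0.35)
  expect_lt(cv$pooled$auc, 0.65)
})

test_that("models survive a save/load round trip with schema checking", {
  f <- separable_features(seed = 8)
  model <- train_rf(f, rf_config(seed = 1), encoders = c("aac", "dde"))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$schema, "aipforest-model-v1")
  expect_equal(sidecar$n_features, 3)
  expect_equal(unlist(sidecar$encoders), c("aac", "dde"))
  back <- load_model(path)
  expect_identical(predict(back, f), predict(model, f))

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(model, bad)
  writeLines('{"schema": "other"}', paste0(bad, ".json"))
  expect_error(load_model(bad), "schema")
})
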