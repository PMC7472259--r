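test_that("feature subsets have the documented widths and contents", {
  f <- fake_features(n_per_group = 2, segments = 3)
  m42 <- build_feature_matrix(f, "all42")
  expect_length(attr(m42, "feature_cols"), 42)
  expect_equal(ncol(m42), 45)  # ids + label + segment + 42 features
  expect_length(feature_subset_columns("ppg18"), 18)
  expect_length(feature_subset_columns("gsr24"), 24)
  expect_length(feature_subset_columns("time8"), 8)
  expect_length(feature_subset_columns("freq10"), 10)
  expect_length(feature_subset_columns("time8+gsr"), 32)
  expect_length(feature_subset_columns("freq10_gsr"), 34)
  expect_error(feature_subset_columns("bogus"),
               class = "pulsefusion_config_error")
})

test_that("the GSR block replicates across a subject's segment rows", {
  cohort <- quick_cohort(n_per_group = 2, duration = 25, seed = 3)
  feats <- suppressMessages(extract_cohort_features(cohort))
  gsr_cols <- feature_subset_columns("gsr24")
  expect_length(feature_subset_columns("all42"), 42)
  per_subject_unique <- feats |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(gsr_cols), dplyr::n_distinct))
  expect_true(all(per_subject_unique[, gsr_cols] == 1))
})

test_that("the FCN separates well-separated clouds and is deterministic", {
  f <- fake_features(n_per_group = 5, segments = 40,
                     shift = list(f1 = 10), seed = 2)
  rows <- build_feature_matrix(f, "time8")
  cfg <- quick_fcn_config(seed = 11)
  fit <- train_fcn(rows, cfg)
  p <- predict(fit, rows)
  acc <- mean((p >= 0.5) == (rows$label == "wiry"))
  expect_gte(acc, 0.99)

  fit2 <- train_fcn(rows, cfg)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(predict(fit2, rows), p)

  single <- rows[rows$label == "wiry", ]
  attr(single, "feature_cols") <- attr(rows, "feature_cols")
  expect_error(train_fcn(single, cfg), class = "pulsefusion_config_error")
})

test_that("tidy and glance describe the fitted network", {
  f <- fake_features(n_per_group = 3, segments = 10, shift = list(f1 = 3))
  fit <- train_fcn(build_feature_matrix(f, "time8"),
                   fcn_config(hidden = c(30, 30, 30), epochs = 5))
  td <- tidy(fit)
  expect_equal(td$n_in, c(8, 30, 30, 30))
  expect_equal(td$n_out, c(30, 30, 30, 1))
  g <- glance(fit)
  expect_equal(g$n_features, 8)
  expect_true(is.finite(g$final_loss))
})

test_that("subject-level folds partition and stratify the cohort", {
  f <- fake_features(n_per_group = 10, segments = 4, shift = list(f2 = 2))
  cv <- cross_validate(f, quick_fcn_config(), k = 5, seed = 3,
                       feature_subset = "time8")
  folds <- cv$folds
  expect_equal(sort(unique(folds$fold)), 1:5)
  expect_equal(nrow(folds), 20)
  expect_equal(anyDuplicated(folds$subject_id), 0)
  per_fold <- table(folds$fold, folds$label)
  expect_true(all(per_fold == 2))  # stratified: 2 per class per fold
  expect_true(all(cv$metrics$n_train_subjects == 16))
  expect_true(all(cv$metrics$n_test_subjects == 4))
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  accs <- vapply(1:3, function(s) {
    f <- fake_features(n_per_group = 8, segments = 15, shift = list(),
                       seed = 100 + s)
    glance(cross_validate(f, quick_fcn_config(seed = s), k = 4,
                          seed = s, feature_subset = "ppg18"))$subject_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})

test_that("standardization is fitted on training folds only (no leakage)", {
  f <- fake_features(n_per_group = 6, segments = 10, shift = list(f1 = 4),
                     seed = 7)
  subjects <- dplyr::distinct(f, subject_id, label)
  folds <- pulsefusion:::make_subject_folds(subjects, 3, seed = 5)
  cv1 <- cross_validate(f, quick_fcn_config(), k = 3, feature_subset = "time8",
                        folds = folds)
  # Corrupt every feature of ONE fold-1 test subject by a huge factor. If any
  # training-state (scaler or weights) saw test data, other subjects'
  # predictions would move; they must not.
  victim <- folds$subject_id[folds$fold == 1][1]
  f2 <- f
  cols <- feature_subset_columns("time8")
  f2[f2$subject_id == victim, cols] <-
    f2[f2$subject_id == victim, cols] * 1000
  cv2 <- cross_validate(f2, quick_fcn_config(), k = 3,
                        feature_subset = "time8", folds = folds)
  # Fold 1 is the only fold whose *training* data exclude the victim; its
  # other test subjects' predictions must be bit-identical.
  keep <- cv1$subject_predictions$fold == 1 &
    cv1$subject_predictions$subject_id != victim
  expect_equal(cv1$subject_predictions$prob[keep],
               cv2$subject_predictions$prob[keep], tolerance = 1e-12)
})

test_that("subject-level accuracy is invariant to segment order", {
  f <- fake_features(n_per_group = 5, segments = 12, shift = list(f3 = 2),
                     seed = 9)
  subjects <- dplyr::distinct(f, subject_id, label)
  folds <- pulsefusion:::make_subject_folds(subjects, 2, seed = 1)
  cv1 <- cross_validate(f, quick_fcn_config(), k = 2, feature_subset = "time8",
                        folds = folds)
  f_shuffled <- f[order(rev(seq_len(nrow(f)))), ]
  cv2 <- cross_validate(f_shuffled, quick_fcn_config(), k = 2,
                        feature_subset = "time8", folds = folds)
  expect_equal(glance(cv1)$subject_accuracy, glance(cv2)$subject_accuracy)
})

test_that("ablation rows share folds and reward the informative modality", {
  f <- fake_features(n_per_group = 8, segments = 10,
                     shift = list(gsr_LU9_left = 2, gsr_LV3_right = 2,
                                  gsr_KD4_left = 2), seed = 4)
  ab <- ablation_table(f, quick_fcn_config(), k = 4, seed = 2,
                       subsets = c("gsr24", "ppg18"))
  expect_equal(ab$feature_subset, c("gsr24", "ppg18"))
  # Signal lives in GSR only: gsr24 must beat ppg18.
  expect_gt(ab$subject_accuracy[1], ab$subject_accuracy[2])
})

test_that("random-forest importance is normalized and finds the signal", {
  f <- fake_features(n_per_group = 10, segments = 10, shift = list(f2 = 2.5),
                     seed = 6)
  imp <- feature_importance(f, num_trees = 300, seed = 8)
  expect_equal(sum(imp$weight), 1, tolerance = 1e-9)
  expect_true(all(imp$weight >= 0))
  expect_equal(imp$feature[1], "f2")
  expect_lt(imp$p_value[imp$feature == "f2"], 0.001)
  # Group stats are on per-subject means.
  expect_equal(imp$wiry_mean[imp$feature == "f2"] -
                 imp$non_wiry_mean[imp$feature == "f2"], 2.5,
               tolerance = 0.6)
})

test_that("pure-noise features share importance roughly uniformly", {
  maxw <- vapply(1:5, function(s) {
    f <- fake_features(n_per_group = 10, segments = 10, shift = list(),
                       seed = 200 + s, subject_sd = 0)
    max(feature_importance(f, num_trees = 200, seed = s)$weight)
  }, numeric(1))
  expect_true(all(maxw < 2 / 42 + 0.05))
})

test_that("holdout evaluation applies the frozen model and scaler", {
  f <- fake_features(n_per_group = 8, segments = 10, shift = list(f1 = 4),
                     seed = 12)
  rows <- build_feature_matrix(f, "time8")
  fit <- train_fcn(rows, quick_fcn_config(seed = 3))

  new_f <- fake_features(n_per_group = 4, segments = 10, shift = list(f1 = 4),
                         seed = 13)
  hv <- evaluate_holdout(fit, build_feature_matrix(new_f, "time8"))
  expect_gte(hv$subject_accuracy, 0.75)

  # A holdout identical to a training subject reproduces its prediction.
  sub1 <- rows[rows$subject_id == rows$subject_id[1], ]
  hv1 <- evaluate_holdout(fit, sub1)
  expect_equal(attr(hv1, "subjects")$prob,
               mean(predict(fit, sub1)))

  expect_error(evaluate_holdout(fit, rows[0, ]),
               class = "pulsefusion_config_error")
  bad <- dplyr::select(rows, -"f1")
  expect_error(evaluate_holdout(fit, bad), class = "pulsefusion_config_error")
})
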