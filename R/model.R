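#' Extract the fused 42-feature table for a cohort
#'
#' Runs the full PPG feature pipeline (bandpass, PMAF, sliding windows, 18
#' per-segment features) for every subject and joins each subject's
#' 24-channel GSR panel onto all of that subject's segment rows (the panel is
#' measured once per subject, so its block is identical across a subject's
#' segments).
#'
#' @param cohort A cohort tibble from [simulate_cohort()] (columns
#'   `subject_id`, `label`, `ppg`, `gsr`).
#' @param ... Passed to [extract_ppg_features()].
#' @return Tibble with one row per segment: `subject_id`, `label`,
#'   `segment_index`, `valid`, the 18 PPG feature columns (`f1..f8`,
#'   `c1..c10`) and 24 `gsr_*` columns.
#' @export
extract_cohort_features <- function(cohort, ...) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    feats <- extract_ppg_features(cohort$ppg[[i]], ...)
    gsr_row <- panel_to_row(cohort$gsr[[i]])
    dplyr::bind_cols(
      tibble(subject_id = cohort$subject_id[i], label = cohort$label[i]),
      feats,
      as_tibble(as.data.frame(as.list(gsr_row)))
    )
  })
  dplyr::bind_rows(rows)
}

#' Feature-subset column sets
#'
#' The seven modality subsets of the ablation experiment. `"all42"` is the
#' fused representation: 18 PPG features (8 time-domain + 10 harmonic) plus
#' the 24 GSR channels.
#'
#' @param subset One of `"all42"`, `"gsr24"`, `"ppg18"`, `"time8"`,
#'   `"freq10"`, `"time8_gsr"`, `"freq10_gsr"` (`"+"` accepted for `"_"`).
#' @return Character vector of feature column names.
#' @export
feature_subset_columns <- function(subset = "all42") {
  subset <- gsub("+", "_", subset, fixed = TRUE)
  time8 <- paste0("f", 1:8)
  freq10 <- paste0("c", 1:10)
  gsr24 <- paste0("gsr_", canonical_gsr_channels())
  switch(subset,
         all42 = c(time8, freq10, gsr24),
         gsr24 = gsr24,
         ppg18 = c(time8, freq10),
         time8 = time8,
         freq10 = freq10,
         time8_gsr = c(time8, gsr24),
         freq10_gsr = c(freq10, gsr24),
         abort(sprintf("Unknown feature subset \"%s\".", subset),
               class = "pulsefusion_config_error"))
}

#' Build the model's feature matrix
#'
#' Filters a cohort feature table to valid, complete rows of the requested
#' modality subset. Subjects with zero usable segments are excluded with a
#' warning. Standardization is *not* applied here: it is fitted on training
#' folds inside [train_fcn()] to avoid leakage.
#'
#' @param features Output of [extract_cohort_features()].
#' @param feature_subset See [feature_subset_columns()].
#' @return Tibble `subject_id`, `label`, `segment_index` plus the subset's
#'   feature columns; the selection is recorded in the `feature_cols`
#'   attribute.
#' @export
build_feature_matrix <- function(features, feature_subset = "all42") {
  cols <- feature_subset_columns(feature_subset)
  valid <- if ("valid" %in% names(features)) features$valid else TRUE
  keep <- valid & stats::complete.cases(features[, cols])
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("Excluding %d invalid/incomplete segment rows.", n_drop))
  }
  out <- features[keep, c("subject_id", "label", "segment_index", cols)]
  lost <- setdiff(unique(features$subject_id), unique(out$subject_id))
  if (length(lost)) {
    warn(sprintf("Subjects with zero valid segments excluded: %s.",
                 paste(lost, collapse = ", ")))
  }
  attr(out, "feature_cols") <- cols
  out
}

# Stratified subject-level fold assignment: within each label, subjects are
# shuffled once and dealt round-robin into k folds.
make_subject_folds <- function(subjects, k, seed) {
  with_seed(seed, {
    subjects |>
      dplyr::group_by(.data$label) |>
      dplyr::group_modify(function(d, g) {
        d <- d[sample.int(nrow(d)), , drop = FALSE]
        d$fold <- rep(seq_len(k), length.out = nrow(d))
        d
      }) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$subject_id)
  })
}

#' Subject-level stratified cross-validation
#'
#' K-fold cross-validation where the folds partition *subjects*, never
#' segments: all 290 segments of a subject land in the same fold, so no
#' subject contributes to both training and test (segment-level splits leak
#' badly because a subject's segments are near-duplicates). Folds are
#' stratified by label, so with 80 balanced subjects and `k = 5` every test
#' fold holds 16 subjects, 8 per class. Accuracy is reported at segment
#' level and at subject level, a subject's call being its mean segment
#' probability thresholded at 0.5.
#'
#' @param features Output of [extract_cohort_features()].
#' @param config An [fcn_config()].
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param feature_subset See [feature_subset_columns()].
#' @param folds Optional precomputed fold tibble (`subject_id`, `label`,
#'   `fold`), e.g. to share folds across ablation rows.
#' @return A `cv_result` with [tidy()] (per fold) and [glance()] (aggregate)
#'   methods.
#' @export
cross_validate <- function(features, config = fcn_config(), k = 5, seed = 1,
                           feature_subset = "all42", folds = NULL) {
  rows <- build_feature_matrix(features, feature_subset)
  subjects <- dplyr::distinct(rows, .data$subject_id, .data$label)
  if (k < 2L || nrow(subjects) < k) {
    abort("Need k >= 2 and at least k subjects.",
          class = "pulsefusion_config_error")
  }
  if (is.null(folds)) folds <- make_subject_folds(subjects, k, seed)
  rows <- dplyr::left_join(rows, folds[, c("subject_id", "fold")],
                           by = "subject_id")

  per_fold <- purrr::map(sort(unique(folds$fold)), function(f) {
    train <- rows[rows$fold != f, , drop = FALSE]
    test <- rows[rows$fold == f, , drop = FALSE]
    attr(train, "feature_cols") <- attr(rows, "feature_cols") %||%
      feature_subset_columns(feature_subset)
    fit <- train_fcn(train, config)
    p <- predict(fit, test)
    y <- as.numeric(test$label == fit$positive_class)
    subj <- tibble(subject_id = test$subject_id, label = test$label,
                   prob = p, truth = y) |>
      dplyr::group_by(.data$subject_id, .data$label) |>
      dplyr::summarise(prob = mean(.data$prob), truth = .data$truth[1],
                       n_segments = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(fold = f, predicted = as.numeric(.data$prob >= 0.5))
    list(
      metrics = tibble(
        fold = f,
        n_train_subjects = dplyr::n_distinct(train$subject_id),
        n_test_subjects = nrow(subj),
        segment_accuracy = mean((p >= 0.5) == y),
        subject_accuracy = mean(subj$predicted == subj$truth)
      ),
      subjects = subj
    )
  })

  structure(list(
    metrics = dplyr::bind_rows(purrr::map(per_fold, "metrics")),
    subject_predictions = dplyr::bind_rows(purrr::map(per_fold, "subjects")),
    folds = folds, k = k, seed = seed, feature_subset = feature_subset,
    config = config
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<cv_result> %s, %d-fold subject-level CV: segment acc %.3f, subject acc %.3f\n",
    x$feature_subset, x$k, g$segment_accuracy, g$subject_accuracy))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) x$metrics

#' @rdname cross_validate
#' @export
glance.cv_result <- function(x, ...) {
  tibble(feature_subset = x$feature_subset, k = x$k,
         n_subjects = nrow(x$folds),
         segment_accuracy = mean(x$metrics$segment_accuracy),
         subject_accuracy = mean(x$metrics$subject_accuracy))
}

#' Modality ablation table
#'
#' Cross-validates each of the seven feature subsets with the *same* fold
#' assignment (a controlled comparison: rows differ only by feature columns)
#' and tabulates segment- and subject-level accuracies.
#'
#' @inheritParams cross_validate
#' @param subsets Character vector of subsets to evaluate.
#' @return Tibble `feature_subset`, `n_features`, `segment_accuracy`,
#'   `subject_accuracy`.
#' @export
ablation_table <- function(features, config = fcn_config(), k = 5, seed = 1,
                           subsets = c("gsr24", "ppg18", "time8", "freq10",
                                       "time8_gsr", "freq10_gsr", "all42")) {
  subjects <- features |>
    dplyr::filter(if ("valid" %in% names(features)) .data$valid else TRUE) |>
    dplyr::distinct(.data$subject_id, .data$label)
  folds <- make_subject_folds(subjects, k, seed)
  purrr::map(subsets, function(s) {
    cv <- cross_validate(features, config, k = k, seed = seed,
                         feature_subset = s, folds = folds)
    dplyr::bind_cols(tibble(n_features = length(feature_subset_columns(s))),
                     glance(cv))[, c("feature_subset", "n_features",
                                     "segment_accuracy", "subject_accuracy")]
  }) |>
    dplyr::bind_rows()
}

#' Random-forest feature importance with group statistics
#'
#' Impurity-based importances from a 500-tree random forest fitted to the
#' segment rows, normalized to sum to 1, together with per-group
#' mean +/- SD of each feature (computed on per-subject averages, so a
#' subject with 290 segments counts once) and a Welch two-sample p-value for
#' the group difference. Constant features get importance 0 and an absent
#' p-value.
#'
#' @param features Output of [extract_cohort_features()].
#' @param feature_subset See [feature_subset_columns()].
#' @param num_trees Number of trees.
#' @param seed Forest seed.
#' @return An `importance_report` tibble: `feature`, `weight`, `rank`,
#'   `wiry_mean`, `wiry_sd`, `non_wiry_mean`, `non_wiry_sd`, `p_value`,
#'   sorted by decreasing weight.
#' @export
feature_importance <- function(features, feature_subset = "all42",
                               num_trees = 500, seed = 1) {
  rows <- build_feature_matrix(features, feature_subset)
  cols <- attr(rows, "feature_cols")
  if (nlevels(droplevels(rows$label)) < 2L) {
    abort("Feature importance needs both classes.",
          class = "pulsefusion_config_error")
  }
  rf <- ranger::ranger(
    x = as.data.frame(rows[, cols]), y = droplevels(rows$label),
    num.trees = num_trees, importance = "impurity", seed = seed,
    num.threads = 1
  )
  imp <- rf$variable.importance[cols]
  imp[is.na(imp) | imp < 0] <- 0
  weight <- if (sum(imp) > 0) imp / sum(imp) else imp

  per_subject <- rows |>
    dplyr::group_by(.data$subject_id, .data$label) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                     .groups = "drop")
  grp_stat <- function(col) {
    w <- per_subject[[col]][per_subject$label == "wiry"]
    nw <- per_subject[[col]][per_subject$label != "wiry"]
    p <- if (sd(per_subject[[col]]) == 0) NA_real_ else {
      tryCatch(t.test(w, nw)$p.value, error = function(e) NA_real_)
    }
    c(wiry_mean = mean(w), wiry_sd = sd(w),
      non_wiry_mean = mean(nw), non_wiry_sd = sd(nw), p_value = p)
  }
  stats_mat <- t(vapply(cols, grp_stat, numeric(5)))
  out <- dplyr::bind_cols(
    tibble(feature = cols, weight = unname(weight)),
    as_tibble(stats_mat)
  ) |>
    dplyr::arrange(dplyr::desc(.data$weight)) |>
    dplyr::mutate(rank = dplyr::row_number(), .after = "weight")
  class(out) <- c("importance_report", class(out))
  out
}

#' @rdname feature_importance
#' @param x An `importance_report`.
#' @param ... Unused.
#' @export
tidy.importance_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "importance_report")
  out
}

#' @rdname feature_importance
#' @export
glance.importance_report <- function(x, ...) {
  tibble(n_features = nrow(x), top_feature = x$feature[1],
         top_weight = x$weight[1],
         n_significant = sum(x$p_value < 0.001, na.rm = TRUE))
}

#' Evaluate a frozen model on held-out subjects
#'
#' Applies a trained classifier (with its frozen training-fold
#' standardization) to new subjects' segment rows and reports accuracy at
#' segment and subject level.
#'
#' @param fit An `fcn_fit` from [train_fcn()].
#' @param features Held-out output of [extract_cohort_features()] (or a
#'   [build_feature_matrix()] table).
#' @return One-row tibble `n_subjects`, `segment_accuracy`,
#'   `subject_accuracy`; per-subject calls in the `subjects` attribute.
#' @export
evaluate_holdout <- function(fit, features) {
  if (nrow(features) == 0L) {
    abort("Empty holdout set.", class = "pulsefusion_config_error")
  }
  rows <- if ("valid" %in% names(features)) {
    keep <- features$valid & stats::complete.cases(features[, fit$feature_cols])
    features[keep, , drop = FALSE]
  } else {
    features
  }
  if (nrow(rows) == 0L) {
    abort("No usable holdout rows.", class = "pulsefusion_config_error")
  }
  p <- predict(fit, rows)
  y <- as.numeric(rows$label == fit$positive_class)
  subj <- tibble(subject_id = rows$subject_id, truth = y, prob = p) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(prob = mean(.data$prob), truth = .data$truth[1],
                     .groups = "drop") |>
    dplyr::mutate(predicted = as.numeric(.data$prob >= 0.5))
  out <- tibble(n_subjects = nrow(subj),
                segment_accuracy = mean((p >= 0.5) == y),
                subject_accuracy = mean(subj$predicted == subj$truth))
  attr(out, "subjects") <- subj
  out
}
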