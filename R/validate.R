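# Performance estimation: confusion-matrix metrics, ROC/AUC, repeated
# k-fold and leave-one-out cross-validation, Monte-Carlo feature
# frequency, random-forest comparison, and class comparison of summary
# statistics.

#' Confusion-matrix metrics and trapezoidal AUC
#'
#' Positive class is `"R"` throughout. AUC is the trapezoidal ROC area
#' over the relapse scores, computed through the rank (Mann--Whitney)
#' identity with midranks, which is exactly the trapezoid rule with the
#' tie-midpoint convention; constant scores give 0.5.
#'
#' @param truth,pred Character vectors in `{"R", "N"}`.
#' @param scores Relapse probabilities/scores (optional; `NULL` skips
#'   AUC).
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `auc`, and the confusion counts `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
#' @examples
#' confusion_metrics(c("R", "R", "N", "N"), c("R", "N", "N", "N"),
#'                   c(0.9, 0.4, 0.2, 0.1))
confusion_metrics <- function(truth, pred, scores = NULL) {
  stopifnot(length(truth) == length(pred))
  if (!all(truth %in% c("R", "N")) || !all(pred %in% c("R", "N"))) {
    stop("labels must be 'R' or 'N'")
  }
  if (!all(c("R", "N") %in% truth)) {
    stop("both classes must be present in the truth labels")
  }
  tp <- sum(truth == "R" & pred == "R")
  tn <- sum(truth == "N" & pred == "N")
  fp <- sum(truth == "N" & pred == "R")
  fn <- sum(truth == "R" & pred == "N")
  auc <- NA_real_
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(truth))
    r <- rank(scores)
    n_r <- sum(truth == "R"); n_n <- sum(truth == "N")
    auc <- (sum(r[truth == "R"]) - n_r * (n_r + 1) / 2) / (n_r * n_n)
  }
  tibble::tibble(
    accuracy = (tp + tn) / length(truth),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    auc = auc, tp = tp, tn = tn, fp = fp, fn = fn)
}

# stratified fold assignment; every training portion keeps >= 2
# patients per class
.make_folds <- function(label, k) {
  fold <- integer(length(label))
  for (cl in unique(label)) {
    idx <- which(label == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated performance of the Fisher classifier
#'
#' Repeated stratified k-fold or leave-one-out cross-validation.
#' Feature selection and model fitting happen inside each training
#' fold only. Per repeat, the out-of-fold predictions of all patients
#' are pooled into one confusion matrix and ROC; the report gives each
#' metric's mean and sd across repeats. LOOCV folds are deterministic,
#' so its repeats coincide (sd 0) unless the classifier itself is
#' randomised.
#'
#' @param features A labelled `percentile_tbl`.
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k Number of folds for `"kfold"`; must not exceed the smaller
#'   class size.
#' @param repeats Number of repetitions. Default 20.
#' @param seed Master seed.
#' @param ... Passed to [fisher_fit()] (threshold, convention, ...).
#' @return An object of class `cv_result`: `$summary` (metric, mean,
#'   sd), `$per_repeat`, `$predictions` (per repeat out-of-fold), plus
#'   the scheme metadata.
#' @export
cross_validate <- function(features, scheme = c("loocv", "kfold"),
                           k = 5, repeats = 20, seed = 1L, ...) {
  scheme <- match.arg(scheme)
  stopifnot(repeats >= 1)
  w <- .feature_wide(features)
  n <- nrow(w$x)
  n_min <- min(table(w$label))
  if (scheme == "kfold" && k > n_min) {
    stop("k = ", k, " exceeds the smaller class size (", n_min,
         "); the maximal number of folds is the number of relapsing ",
         "patients")
  }
  if (n_min < 3) stop("need at least 3 patients in each class")
  pid <- rownames(w$x)
  per_repeat <- vector("list", repeats)
  preds <- vector("list", repeats)
  .with_seed(seed, for (r in seq_len(repeats)) {
    fold <- if (scheme == "loocv") seq_len(n) else .make_folds(w$label, k)
    out <- vector("list", max(fold))
    for (fd in sort(unique(fold))) {
      test_id <- pid[fold == fd]
      train <- features[!features$patient_id %in% test_id, ]
      test <- features[features$patient_id %in% test_id, ]
      model <- fisher_fit(train, ...)
      out[[fd]] <- predict(model, test)
    }
    pr <- dplyr::bind_rows(out)
    per_repeat[[r]] <- dplyr::bind_cols(
      tibble::tibble(repeat_id = r),
      confusion_metrics(pr$label, pr$pred, pr$prob_relapse))
    preds[[r]] <- dplyr::bind_cols(tibble::tibble(repeat_id = r), pr)
  })
  per_repeat <- dplyr::bind_rows(per_repeat)
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
               "auc")
  summary <- tibble::tibble(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_repeat[[m]]), 0,
                  USE.NAMES = FALSE),
    sd = vapply(metrics, function(m) stats::sd(per_repeat[[m]]), 0,
                USE.NAMES = FALSE))
  if (repeats == 1) summary$sd <- 0
  structure(list(summary = summary, per_repeat = per_repeat,
                 predictions = dplyr::bind_rows(preds),
                 scheme = scheme, k = if (scheme == "kfold") k else n,
                 repeats = repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$scheme, " (k = ", x$k, "), ", x$repeats,
      " repeats\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  out <- tibble::as_tibble(as.list(stats::setNames(x$summary$mean,
                                                   x$summary$metric)))
  out$scheme <- x$scheme
  out$repeats <- x$repeats
  out
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$summary

# stratified train/test split of patient ids
.split_cohort <- function(pid, label, train_fraction) {
  train <- unlist(lapply(unique(label), function(cl) {
    idx <- pid[label == cl]
    n_tr <- max(2L, round(length(idx) * train_fraction))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
    sample(idx, n_tr)
  }))
  train
}

#' Monte-Carlo feature (marker) frequency analysis
#'
#' Draws repeated stratified train/test splits, fits a Fisher
#' classifier on each training portion, records its test accuracy and
#' the markers its selected features use, then reports -- for each
#' accuracy threshold -- how often every marker was used among the
#' classifiers at or above that threshold.
#'
#' @param features Labelled `percentile_tbl`.
#' @param n_splits Number of random splits. Default 100.
#' @param train_fraction Training fraction. Default 0.75.
#' @param accuracy_thresholds Numeric thresholds. Default
#'   `c(0, 0.5, 0.7, 0.8)`.
#' @param seed Master seed.
#' @param ... Passed to [fisher_fit()].
#' @return An object of class `feature_frequency`: `$frequencies`
#'   (threshold, marker, frequency, n_classifiers) and `$splits`
#'   (per-split accuracy and markers). Thresholds that no classifier
#'   reaches yield zero rows with a warning.
#' @export
feature_frequency <- function(features, n_splits = 100,
                              train_fraction = 0.75,
                              accuracy_thresholds = c(0, 0.5, 0.7, 0.8),
                              seed = 1L, ...) {
  stopifnot(n_splits >= 1, train_fraction > 0, train_fraction < 1)
  w <- .feature_wide(features)
  pid <- rownames(w$x)
  splits <- vector("list", n_splits)
  .with_seed(seed, for (s in seq_len(n_splits)) {
    train_id <- .split_cohort(pid, w$label, train_fraction)
    train <- features[features$patient_id %in% train_id, ]
    test <- features[!features$patient_id %in% train_id, ]
    model <- fisher_fit(train, ...)
    pr <- predict(model, test)
    acc <- mean(pr$pred == pr$label)
    used <- unique(model$features$marker[model$features$selected])
    splits[[s]] <- tibble::tibble(split = s, accuracy = acc,
                                  marker = used)
  })
  splits <- dplyr::bind_rows(splits)
  freqs <- lapply(accuracy_thresholds, function(th) {
    qual <- unique(splits$split[splits$accuracy >= th])
    if (length(qual) == 0) {
      warning("no classifier reaches accuracy threshold ", th)
      return(tibble::tibble(threshold = numeric(), marker = character(),
                            frequency = numeric(),
                            n_classifiers = integer()))
    }
    sub <- splits[splits$split %in% qual, ]
    sub |>
      dplyr::count(.data$marker) |>
      dplyr::transmute(threshold = th, marker = .data$marker,
                       frequency = .data$n / length(qual),
                       n_classifiers = length(qual))
  })
  structure(list(frequencies = dplyr::bind_rows(freqs),
                 splits = splits, n_splits = n_splits,
                 train_fraction = train_fraction, seed = seed),
            class = "feature_frequency")
}

#' @export
print.feature_frequency <- function(x, ...) {
  cat("<feature_frequency> ", x$n_splits, " splits at ",
      round(100 * x$train_fraction), ":",
      round(100 * (1 - x$train_fraction)), "\n", sep = "")
  print(x$frequencies)
  invisible(x)
}

#' Random-forest comparison runs
#'
#' Repeated random-forest fits on stratified train splits over the
#' flattened percentile matrix, reporting the out-of-bag (OOB)
#' classification error trace and per-marker permutation importance
#' (mean decrease in accuracy, summed over each marker's percentile
#' features so total importance is preserved).
#'
#' @param features Labelled `percentile_tbl`.
#' @param n_runs Number of runs. Default 100.
#' @param n_trees Trees per forest. Default 50.
#' @param train_fraction Stratified training fraction. Default 0.75.
#' @param seed Master seed.
#' @return An object of class `rf_comparison`: `$oob` (run, oob_error),
#'   `$importance` (run, marker, importance), `$summary`.
#' @export
random_forest_comparison <- function(features, n_runs = 100,
                                     n_trees = 50,
                                     train_fraction = 0.75, seed = 1L) {
  w <- .feature_wide(features)
  pid <- rownames(w$x)
  oob <- numeric(n_runs)
  imp <- vector("list", n_runs)
  .with_seed(seed, for (r in seq_len(n_runs)) {
    train_id <- .split_cohort(pid, w$label, train_fraction)
    tr <- match(train_id, pid)
    y <- factor(w$label[tr], levels = c("N", "R"))
    fit <- randomForest::randomForest(
      x = w$x[tr, , drop = FALSE], y = y, ntree = n_trees,
      importance = TRUE)
    oob[r] <- fit$err.rate[n_trees, "OOB"]
    mda <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
    imp[[r]] <- tibble::tibble(run = r, marker = w$marker,
                               importance = mda) |>
      dplyr::group_by(.data$run, .data$marker) |>
      dplyr::summarise(importance = sum(.data$importance),
                       .groups = "drop")
  })
  imp <- dplyr::bind_rows(imp)
  top <- imp |>
    dplyr::group_by(.data$run) |>
    dplyr::slice_max(.data$importance, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  structure(list(
    oob = tibble::tibble(run = seq_len(n_runs), oob_error = oob),
    importance = imp,
    summary = tibble::tibble(
      mean_oob = mean(oob), sd_oob = stats::sd(oob),
      top_marker = names(sort(table(top$marker), decreasing = TRUE))[1]),
    n_runs = n_runs, n_trees = n_trees, seed = seed),
    class = "rf_comparison")
}

#' @export
print.rf_comparison <- function(x, ...) {
  cat("<rf_comparison> ", x$n_runs, " forests x ", x$n_trees,
      " trees: OOB error ", sprintf("%.3f +/- %.3f", x$summary$mean_oob,
                                    x$summary$sd_oob),
      ", top marker ", x$summary$top_marker, "\n", sep = "")
  invisible(x)
}

#' Class comparison of per-patient summary statistics
#'
#' Two-sample t-tests (Welch by default) between relapse and
#' non-relapse patients, per marker, on the per-patient median, mean
#' and standard deviation -- and on the fitted generalized-logistic
#' parameters `alpha` and `gamma` when fits are supplied. Flags at
#' p < 0.05 with no multiplicity correction (a Benjamini--Hochberg
#' column is available via `adjust`).
#'
#' @param summaries Tibble from [marker_summaries()] on a `sample_set`
#'   (columns `patient_id`, `label`, `marker`, `median`, `mean`, `sd`).
#' @param fits Optional tibble from [fit_cohort_logistic()].
#' @param var_equal Pooled-variance t-test instead of Welch. Default
#'   `FALSE`.
#' @param adjust Add a BH-adjusted p-value column. Default `FALSE`.
#' @return Tibble: `marker`, `statistic`, `estimate_r`, `estimate_n`,
#'   `t`, `p`, `flag` (p < 0.05), optionally `p_adj`. Statistics with
#'   zero within-class variance are skipped with a note column.
#' @export
compare_summaries <- function(summaries, fits = NULL,
                              var_equal = FALSE, adjust = FALSE) {
  long <- summaries |>
    tidyr::pivot_longer(cols = c("median", "mean", "sd"),
                        names_to = "statistic", values_to = "value")
  if (!is.null(fits)) {
    long <- dplyr::bind_rows(
      long,
      fits |>
        tidyr::pivot_longer(cols = c("alpha", "gamma"),
                            names_to = "statistic",
                            values_to = "value") |>
        dplyr::select(dplyr::all_of(c("patient_id", "label", "marker",
                                      "statistic", "value"))))
  }
  out <- long |>
    dplyr::group_by(.data$marker, .data$statistic) |>
    dplyr::group_modify(function(d, key) {
      vr <- d$value[d$label == "R"]; vn <- d$value[d$label == "N"]
      if (length(vr) < 2 || length(vn) < 2 ||
          (stats::sd(vr) == 0 && stats::sd(vn) == 0)) {
        return(tibble::tibble(estimate_r = mean(vr),
                              estimate_n = mean(vn),
                              t = NA_real_, p = NA_real_, flag = NA,
                              note = "skipped: zero variance or n < 2"))
      }
      tt <- stats::t.test(vr, vn, var.equal = var_equal)
      tibble::tibble(estimate_r = mean(vr), estimate_n = mean(vn),
                     t = unname(tt$statistic), p = tt$p.value,
                     flag = tt$p.value < 0.05, note = NA_character_)
    }) |>
    dplyr::ungroup()
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
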