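test_that("confusion metrics reproduce the hand-computed example", {
  truth <- c("R", "R", "N", "N")
  pred <- c("R", "N", "N", "N")
  m <- confusion_metrics(truth, pred, c(0.9, 0.4, 0.3, 0.1))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$ppv, 1.0)
  expect_equal(m$npv, 2 / 3)
  expect_equal(m$auc, 1.0)  # scores order the classes perfectly
})

test_that("AUC handles degenerate and tied scores", {
  truth <- c("R", "R", "N", "N", "N")
  expect_equal(confusion_metrics(truth, truth,
                                 rep(0.3, 5))$auc, 0.5)
  expect_equal(confusion_metrics(truth, truth,
                                 c(5, 4, 3, 2, 1))$auc, 1)
  expect_equal(confusion_metrics(truth, truth,
                                 c(1, 2, 3, 4, 5))$auc, 0)
})

test_that("AUC and metrics agree with independent computations", {
  set.seed(21)
  for (i in 1:10) {
    n <- 20
    truth <- sample(c("R", "N"), n, replace = TRUE,
                    prob = c(0.3, 0.7))
    if (length(unique(truth)) < 2) next
    pred <- sample(c("R", "N"), n, replace = TRUE)
    scores <- round(runif(n), 1)  # force ties
    got <- confusion_metrics(truth, pred, scores)
    orc <- oracle_metrics(truth, pred, scores)
    for (k in c("accuracy", "sensitivity", "specificity", "auc")) {
      expect_equal(got[[k]], orc[[k]], label = k)
    }
    # cross-check AUC against pROC (independent library route)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("N", "R"),
      direction = "<", quiet = TRUE)))
    expect_equal(got$auc, proc_auc)
  }
})

test_that("metric identities hold on stored confusion counts", {
  set.seed(22)
  truth <- sample(rep(c("R", "N"), c(6, 14)))
  pred <- sample(c("R", "N"), 20, replace = TRUE)
  m <- confusion_metrics(truth, pred, runif(20))
  expect_equal(m$accuracy, (m$tp + m$tn) / 20)
  expect_equal(m$sensitivity * 6 + m$specificity * 14, m$tp + m$tn)
  expect_equal(m$ppv, m$tp / (m$tp + m$fp))
  expect_equal(m$npv, m$tn / (m$tn + m$fn))
})

test_that("degenerate truth vectors are rejected", {
  expect_error(confusion_metrics(c("R", "R"), c("R", "N")), "both classes")
  expect_error(confusion_metrics(c("R", "N"), c("R", "X")), "labels")
})

test_that("LOOCV produces one out-of-fold prediction per patient", {
  sep <- separable_features(n_r = 4, n_n = 8)
  cv <- cross_validate(sep, "loocv", repeats = 2, seed = 1)
  expect_equal(nrow(cv$predictions), 2 * 12)
  expect_equal(sort(table(cv$predictions$patient_id)),
               sort(rep(2, 12)), ignore_attr = TRUE)
})

test_that("perfectly separated classes give accuracy and AUC 1", {
  sep <- separable_features(n_r = 5, n_n = 9)
  for (scheme in c("loocv", "kfold")) {
    cv <- cross_validate(sep, scheme, k = 4, repeats = 3, seed = 2)
    expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"], 1)
    expect_equal(cv$summary$mean[cv$summary$metric == "auc"], 1)
  }
})

test_that("k beyond the smaller class size is refused", {
  sep <- separable_features(n_r = 4, n_n = 8)
  expect_error(cross_validate(sep, "kfold", k = 5, seed = 1),
               "smaller class")
})

test_that("cross-validation is reproducible under a fixed seed", {
  sep <- separable_features(n_r = 5, n_n = 9)
  a <- cross_validate(sep, "kfold", k = 3, repeats = 4, seed = 9)
  b <- cross_validate(sep, "kfold", k = 3, repeats = 4, seed = 9)
  expect_identical(a$summary, b$summary)
  expect_identical(a$predictions, b$predictions)
})

test_that("fold models never see the held-out patients", {
  set.seed(23)
  inst <- random_instance(n_r = 4, n_n = 6, n_marker = 2, n_level = 3)
  all_feat <- inst$features
  test_ids <- c("P01", "P02")
  train <- all_feat[!all_feat$patient_id %in% test_ids, ]
  m_direct <- fisher_fit(train)
  # perturbing the held-out patients' values must not change the model
  poisoned <- all_feat
  poisoned$value[poisoned$patient_id %in% test_ids] <- 99
  m_poisoned <- fisher_fit(
    poisoned[!poisoned$patient_id %in% test_ids, ])
  expect_identical(m_direct$features, m_poisoned$features)
})

test_that("feature frequency recovers a planted marker", {
  sep <- separable_features(n_r = 5, n_n = 11, n_noise = 4)
  ffq <- feature_frequency(sep, n_splits = 30,
                           accuracy_thresholds = c(0, 1.1), seed = 3)
  f0 <- ffq$frequencies[ffq$frequencies$threshold == 0, ]
  expect_gte(f0$frequency[f0$marker == "CD38"], 0.9)
  expect_equal(unique(f0$n_classifiers), 30)
})

test_that("an impossible accuracy threshold yields an empty table", {
  sep <- separable_features()
  expect_warning(
    ffq <- feature_frequency(sep, n_splits = 5,
                             accuracy_thresholds = 1.1, seed = 4),
    "no classifier")
  expect_equal(nrow(ffq$frequencies), 0)
})

test_that("random forests find the planted marker and stabilise", {
  sep <- separable_features(n_r = 6, n_n = 12, n_noise = 5)
  rf <- random_forest_comparison(sep, n_runs = 10, n_trees = 50,
                                 seed = 5)
  expect_identical(rf$summary$top_marker, "CD38")
  expect_true(all(rf$oob$oob_error >= 0 & rf$oob$oob_error <= 1))
  rf1 <- random_forest_comparison(sep, n_runs = 10, n_trees = 1,
                                  seed = 5)
  expect_lte(rf$summary$sd_oob, rf1$summary$sd_oob)
})

test_that("summary comparisons match a brute-force t statistic", {
  set.seed(24)
  summaries <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    label = rep(c("R", "N"), each = 5),
    marker = "CD38",
    median = c(rnorm(5, 0.4), rnorm(5, 0.6)),
    mean = rnorm(10, 0.5),
    sd = runif(10, 0.1, 0.2))
  tab <- compare_summaries(summaries)
  med <- tab[tab$statistic == "median", ]
  t_orc <- oracle_welch_t(summaries$median[summaries$label == "R"],
                          summaries$median[summaries$label == "N"])
  expect_equal(med$t, t_orc)
  expect_identical(med$flag, med$p < 0.05)
  tab_bh <- compare_summaries(summaries, adjust = TRUE)
  expect_true("p_adj" %in% names(tab_bh))
})

test_that("zero-variance statistics are skipped with a note", {
  summaries <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:8),
    label = rep(c("R", "N"), each = 4),
    marker = "A",
    median = rep(0.5, 8), mean = rnorm(8), sd = runif(8))
  tab <- compare_summaries(summaries)
  expect_true(is.na(tab$p[tab$statistic == "median"]))
  expect_match(tab$note[tab$statistic == "median"], "skipped")
})

test_that("fitted-parameter comparisons are included when supplied", {
  set.seed(25)
  summaries <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:8),
    label = rep(c("R", "N"), each = 4), marker = "CD38",
    median = rnorm(8), mean = rnorm(8), sd = runif(8))
  fits <- tibble::tibble(
    patient_id = summaries$patient_id, label = summaries$label,
    marker = "CD38", a = runif(8), alpha = rnorm(8, 5),
    gamma = rnorm(8, 1, 0.1), rss = runif(8), converged = TRUE)
  tab <- compare_summaries(summaries, fits = fits)
  expect_setequal(unique(tab$statistic),
                  c("median", "mean", "sd", "alpha", "gamma"))
})
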