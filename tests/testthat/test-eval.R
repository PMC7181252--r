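# ROC/EER metrics and the two cross-validation schemes.

test_that("roc_metrics matches the pairwise Mann-Whitney oracle", {
  # perfect separation
  m <- roc_metrics(c(0.9, 0.1), c(1, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$eer, 0)
  expect_equal(m$gm, 1)

  expect_error(roc_metrics(runif(5), rep(1, 5)), "one class")

  fogkit:::with_seed(14, {
    for (rep_i in 1:5) {
      n <- 20
      scores <- round(runif(n), 1)          # rounding forces ties
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      m <- roc_metrics(scores, labels)
      expect_equal(m$auc, oracle_auc_pairs(scores, labels), tolerance = 1e-12)
      # reversing scores flips the AUC
      expect_equal(roc_metrics(-scores, labels)$auc, 1 - m$auc,
                   tolerance = 1e-12)
      # reported point metrics are consistent
      expect_equal(m$gm, sqrt(m$sensitivity * m$specificity))
      n1 <- sum(labels); n0 <- sum(!labels)
      expect_lte(abs(m$sensitivity - (1 - m$eer)), 1 / min(n1, n0))
      expect_true(m$auc >= 0 && m$auc <= 1)
    }
  })
})

test_that("equal-error point minimizes |sensitivity - specificity|", {
  scores <- c(0.1, 0.2, 0.35, 0.4, 0.55, 0.6, 0.8, 0.9)
  labels <- c(0, 0, 1, 0, 0, 1, 1, 1)
  m <- roc_metrics(scores, labels)
  # exhaustive sweep over thresholds between consecutive scores
  best <- Inf
  for (thr in c(sort(unique(scores)), Inf)) {
    sens <- mean(scores[labels == 1] >= thr)
    spec <- mean(scores[labels == 0] < thr)
    best <- min(best, abs(sens - spec))
  }
  expect_equal(abs(m$sensitivity - m$specificity), best, tolerance = 1e-12)
})

test_that("LOSO evaluates every subject per repeat with disjoint folds", {
  fm <- small_cohort_features("fft", 0)
  expect_error(loso_evaluate(fogkit:::features_subset(fm, fm$subject_id == "S01"),
                             "random_forest"), "at least 2")
  ev <- loso_evaluate(fm, "random_forest", repeats = 2, seed = 5,
                      n_estimators = 30)
  expect_s3_class(ev, "fog_eval")
  expect_equal(nrow(ev$per_fold), 2 * 3)
  expect_setequal(unique(ev$per_fold$subject), unique(fm$subject_id))
  # aggregate is the arithmetic mean of the per-fold metrics
  expect_equal(unname(ev$aggregate["auc"]), mean(ev$per_fold$auc))
  # per-fold score vectors cover exactly the held-out subject's windows
  for (i in seq_along(ev$scores)) {
    sub <- ev$scores[[i]]$subject
    expect_length(ev$scores[[i]]$scores, sum(fm$subject_id == sub))
  }
  # aggregate AUC reproducible from the persisted per-fold scores
  re_auc <- mean(sapply(ev$scores, function(sl)
    roc_metrics(sl$scores, sl$labels)$auc))
  expect_equal(unname(ev$aggregate["auc"]), re_auc, tolerance = 1e-12)
})

test_that("R10fold partitions windows once each and reports overlap leakage", {
  fm <- small_cohort_features("fft", 0)
  one <- fogkit:::features_subset(fm, fm$subject_id == "S01")
  expect_error(r10fold_evaluate(fm, "random_forest"), "one subject")
  expect_error(r10fold_evaluate(fogkit:::features_subset(one, 1:5),
                                "random_forest"), "at least")

  ev <- r10fold_evaluate(one, "random_forest", seed = 7, n_estimators = 30)
  expect_equal(sort(unique(ev$fold_id)), 1:10)
  expect_length(ev$fold_id, nrow(one$values))  # every window in exactly 1 fold
  # stratification keeps both classes in each fold when counts allow
  expect_true(all(table(ev$fold_id, one$labels) > 0))

  # with 75% overlap, train and test share raw samples
  expect_gt(ev$leakage$shared_fraction, 0)
  expect_gt(ev$leakage$mean_shared_train_windows, 0)

  # fold assignment is reproducible from the seed
  ev2 <- r10fold_evaluate(one, "random_forest", seed = 7, n_estimators = 30)
  expect_identical(ev$fold_id, ev2$fold_id)
  expect_equal(ev$aggregate, ev2$aggregate, tolerance = 1e-9)

  # grouped (contiguous-block) splitting removes almost all sharing
  evg <- r10fold_evaluate(one, "random_forest", seed = 7, n_estimators = 30,
                          grouped = TRUE)
  expect_lt(evg$leakage$shared_fraction, ev$leakage$shared_fraction)
})

test_that("report writes deterministic artifacts regenerable from scores", {
  fm <- small_cohort_features("fft", 0)
  ev <- loso_evaluate(fm, "random_forest", repeats = 1, seed = 5,
                      n_estimators = 30)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  p1 <- report(ev, d1)
  expect_true(all(file.exists(p1)))
  stem <- "loso_random_forest_fft_k0"
  expect_true(any(grepl(paste0(stem, "_folds.csv"), p1)))
  p2 <- report(ev, d2)
  f1 <- file.path(d1, paste0(stem, "_folds.csv"))
  f2 <- file.path(d2, paste0(stem, "_folds.csv"))
  expect_identical(readLines(f1), readLines(f2))    # byte-identical tables
  roc <- utils::read.csv(file.path(d1, paste0(stem, "_roc.csv")))
  expect_true(all(diff(roc$tpr) >= -1e-9))          # mean ROC is monotone
})
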