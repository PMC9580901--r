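test_that("confusion metrics match the worked example and the formula oracle", {
  # TP=3, TN=3, FP=1, FN=1
  preds <- data.frame(class = c(1, 1, 1, -1, -1, -1, 1, -1),
                      posterior = rep(0.9, 8))
  labels <- c(1, 1, 1, -1, -1, -1, -1, 1)
  m <- evaluate_predictions(preds, labels)
  expect_equal(m$acc, 0.75)
  expect_equal(m$prec, 0.75)
  expect_equal(m$rec, 0.75)
  expect_equal(m$mcc, 0.5)
  expect_equal(m$npv, 0.75)

  # sampled confusion matrices vs the independent formula oracle
  set.seed(99)
  for (i in 1:50) {
    cm <- as.list(sample(0:8, 4, replace = TRUE))
    names(cm) <- c("tp", "tn", "fp", "fn")
    if (sum(unlist(cm)) == 0) next
    cls <- c(rep(1, cm$tp), rep(-1, cm$tn), rep(1, cm$fp), rep(-1, cm$fn))
    lab <- c(rep(1, cm$tp), rep(-1, cm$tn), rep(-1, cm$fp), rep(1, cm$fn))
    got <- evaluate_predictions(data.frame(class = cls, posterior = 0.8), lab)
    want <- do.call(oracle_metrics, cm)
    for (metric in names(want)) expect_equal(got[[metric]], want[[metric]])
  }
})

test_that("degenerate predictors flag undefined ratios as 0", {
  m <- evaluate_predictions(
    data.frame(class = rep(1, 6), posterior = 0.7),
    rep(c(1, -1), 3))
  expect_equal(m$rec, 1)
  expect_equal(m$mcc, 0)
  expect_true("npv" %in% m$undefined)
  expect_error(evaluate_predictions(data.frame(class = 1, posterior = 0.7),
                                    c(1, -1)), "mismatch")
})

test_that("rank-formula ROC AUC agrees with pROC and the U statistic", {
  library(pROC)
  set.seed(123)
  for (i in 1:10) {
    n <- 40
    labels <- sample(c(-1, 1), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + 0.8 * (labels == 1)
    got <- roc_auc(scores, labels)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<", levels = c(-1, 1))))
    expect_equal(got, ref, tolerance = 1e-12)
    # Mann-Whitney U normalization
    u <- wilcox.test(scores[labels == 1], scores[labels == -1],
                     exact = FALSE)$statistic
    expect_equal(got, unname(u) / (sum(labels == 1) * sum(labels == -1)),
                 tolerance = 1e-12)
  }
  # average precision sanity: perfect ranking -> 1
  expect_equal(pr_auc(c(3, 2, 1), c(1, 1, -1)), 1)
  expect_equal(pr_auc(c(1, 2, 3), c(1, -1, -1)), 1 / 3)
})

test_that("well-separated classes are learned by all three families", {
  ds <- make_shifted_dataset(n_per = 30, shift = 2, rng_seed = 7)
  for (kind in c("SVM", "RF", "NN")) {
    b <- train_model(ds, kind, grid = small_grids[[kind]], rng_seed = 7)
    mean_auc <- b$cv_report$roc_auc[is.na(b$cv_report$fold)]
    expect_gte(mean_auc, 0.95)
    # best params are members of the supplied grid
    for (pn in names(small_grids[[kind]])) {
      expect_true(b$best_params[[pn]] %in% small_grids[[kind]][[pn]])
    }
    expect_equal(nrow(b$cv_report), 6)  # 5 folds + mean row
  }
})

test_that("label permutation collapses CV AUC to chance", {
  ds <- permute_labels(make_shifted_dataset(30, 2, rng_seed = 11), 11)
  b <- train_model(ds, "RF", grid = small_grids$RF, rng_seed = 11)
  mean_auc <- b$cv_report$roc_auc[is.na(b$cv_report$fold)]
  expect_lt(abs(mean_auc - 0.5), 0.15)
})

test_that("training is reproducible and rejects degenerate datasets", {
  ds <- make_shifted_dataset(15, 1.5, rng_seed = 3)
  b1 <- train_model(ds, "NN", grid = small_grids$NN, rng_seed = 3)
  b2 <- train_model(ds, "NN", grid = small_grids$NN, rng_seed = 3)
  expect_identical(b1$cv_report, b2$cv_report)
  expect_identical(b1$best_params, b2$best_params)

  single <- ds; single$data$label <- 1L
  expect_error(train_model(single, "RF"), "single class")
  tiny <- ds; tiny$data <- ds$data[1:6, ]
  expect_error(train_model(tiny, "RF"), "fewer than 10 rows")
})

test_that("predictions carry predicted-class posteriors >= 0.5", {
  ds <- make_shifted_dataset(20, 2, rng_seed = 5)
  sp <- split_dataset(ds, 0.3, 5)
  for (kind in c("SVM", "RF", "NN")) {
    b <- train_model(sp$train, kind, grid = small_grids[[kind]], rng_seed = 5)
    fv <- sp$test$data[feature_names()]
    rownames(fv) <- sp$test$data$accession
    p1 <- predict_model(b, fv)
    p2 <- predict_model(b, fv)
    expect_identical(p1, p2)
    expect_true(all(p1$posterior >= 0.5 & p1$posterior <= 1))
    expect_true(all(p1$class == ifelse(p1$p_pos >= 0.5, 1, -1)))
    expect_true(all(p1$class %in% c(-1, 1)))
  }
  b <- train_model(sp$train, "RF", grid = small_grids$RF, rng_seed = 5)
  bad <- sp$test$data[1, feature_names()]
  bad$guild_score <- NA_real_
  expect_error(predict_model(b, bad), "non-finite")
})

test_that("select_best_model applies the tie-break chain", {
  reports <- data.frame(diamond_threshold = c(0.9, 0.8, 0.8, 0.6),
                        neg_ratio = c(1, 3, 1, 1),
                        mean_roc_auc = c(0.80, 0.85, 0.85, 0.70))
  best <- select_best_model(reports)
  expect_equal(best$neg_ratio, 1)          # tie on AUC -> smaller ratio
  expect_equal(best$diamond_threshold, 0.8)
  single <- reports[4, ]
  expect_equal(select_best_model(single)$diamond_threshold, 0.6)
  expect_error(select_best_model(reports[0, ]), "no reports")
})

test_that("stratified folds keep both classes in every fold", {
  labels <- rep(c(1, -1), c(12, 18))
  f <- stratified_folds(labels, 5, rng_seed = 2)
  for (k in 1:5) {
    expect_setequal(unique(labels[f == k]), c(1, -1))
  }
  expect_error(stratified_folds(rep(c(1, -1), c(3, 20)), 5), "fewer rows")
})
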