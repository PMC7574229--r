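# Separable synthetic window features for the classifier tests: each class
# occupies its own region of a 6-D feature space, with hour-scale structure.
make_separable <- function(n_hours = 20, per_hour = 30, seed = 50,
                           noise = 0.3) {
  set.seed(seed)
  classes <- c("grazing", "walking", "standing", "lying")
  centers <- matrix(c(3, 0, 0, 0, 3, 0,
                      0, 3, 0, 3, 0, 0,
                      0, 0, 3, 0, 0, 3,
                      3, 3, 3, 0, 0, 0), 4, 6, byrow = TRUE)
  hour <- rep(seq_len(n_hours), each = per_hour)
  lab <- sample(classes, n_hours * per_hour, replace = TRUE)
  X <- centers[match(lab, classes), ] + matrix(rnorm(length(lab) * 6, 0, noise),
                                               ncol = 6)
  colnames(X) <- paste0("f", 1:6)
  rum <- lab %in% c("standing", "lying") & X[, 1] + rnorm(length(lab), 0, 0.1) > 1.5
  list(X = X, lab = lab, rum = rum, hour = hour)
}

test_that("hour-blocked splitting keeps hours disjoint and reproducible", {
  hk <- rep(1:10, each = 7)
  sp <- hour_blocked_split(hk, 0.2, seed = 5)
  expect_length(unique(hk[sp$test]), 2)
  expect_length(unique(hk[sp$train]), 8)
  expect_length(intersect(unique(hk[sp$train]), unique(hk[sp$test])), 0)
  expect_identical(sp, hour_blocked_split(hk, 0.2, seed = 5))
  expect_error(hour_blocked_split(rep(1, 5)), "at least 2")
  # 1000 random windows: no window's hour on both sides
  set.seed(51)
  hk2 <- sample(100:140, 1000, replace = TRUE)
  sp2 <- hour_blocked_split(hk2, 0.2, seed = 6)
  expect_length(intersect(hk2[sp2$train], hk2[sp2$test]), 0)
})

test_that("cross-validation folds are hour-disjoint with near-equal hour counts", {
  hk <- rep(1:25, each = 3)
  f <- cv_folds_by_hour(hk, k = 5, seed = 7)
  expect_length(f, length(hk))
  hours_per_fold <- vapply(1:5, function(i) length(unique(hk[f == i])), numeric(1))
  expect_equal(hours_per_fold, rep(5, 5))
  for (i in 1:5) {
    expect_length(intersect(unique(hk[f == i]), unique(hk[f != i])), 0)
  }
  expect_identical(f, cv_folds_by_hour(hk, k = 5, seed = 7))
  expect_error(cv_folds_by_hour(rep(1:3, 2), k = 5), "fewer")
})

test_that("mean balanced accuracy follows the one-vs-rest definition", {
  expect_equal(mean_balanced_accuracy(c("a", "b", "a"), c("a", "b", "a")), 1)
  # binary confusion TP=40 FN=10 TN=30 FP=20 -> 0.7 for both classes
  truth <- c(rep("pos", 50), rep("neg", 50))
  pred <- c(rep("pos", 40), rep("neg", 10), rep("pos", 20), rep("neg", 30))
  expect_equal(mean_balanced_accuracy(truth, pred), 0.7)
  # constant prediction on balanced binary data -> 0.5
  expect_equal(mean_balanced_accuracy(truth, rep("pos", 100)), 0.5)
  expect_error(mean_balanced_accuracy(c("a", "a"), c("a", "a"),
                                      classes = c("a", "b")),
               "no positive instance")
})

test_that("the metric suite matches textbook formulas on a random confusion table", {
  expect_equal(unname(metric_suite(c("a", "b"), c("a", "b"))$overall),
               c(1, 1, 1))
  set.seed(52)
  classes <- c("a", "b", "c")
  truth <- sample(classes, 400, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  pred <- ifelse(runif(400) < 0.6, truth, sample(classes, 400, replace = TRUE))
  ms <- metric_suite(truth, pred)
  n <- 400
  cm <- table(truth, pred)
  expect_equal(unname(ms$overall["accuracy"]), sum(diag(cm)) / n, tolerance = 1e-12)
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  expect_equal(unname(ms$overall["kappa"]),
               (sum(diag(cm)) / n - pe) / (1 - pe), tolerance = 1e-12)
  # Gorodkin MCC
  num <- n * sum(diag(cm)) - sum(rowSums(cm) * colSums(cm))
  den <- sqrt(n^2 - sum(colSums(cm)^2)) * sqrt(n^2 - sum(rowSums(cm)^2))
  expect_equal(unname(ms$overall["mcc"]), num / den, tolerance = 1e-12)
  for (cl in classes) {
    tp <- cm[cl, cl]; fn <- sum(cm[cl, ]) - tp; fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    expect_equal(unname(ms$per_class[cl, "recall"]), tp / (tp + fn), tolerance = 1e-12)
    expect_equal(unname(ms$per_class[cl, "precision"]), tp / (tp + fp), tolerance = 1e-12)
    expect_equal(unname(ms$per_class[cl, "tnr"]), tn / (tn + fp), tolerance = 1e-12)
    expect_equal(unname(ms$per_class[cl, "npv"]), tn / (tn + fn), tolerance = 1e-12)
    expect_equal(unname(ms$per_class[cl, "f1"]),
                 2 * tp / (2 * tp + fp + fn), tolerance = 1e-12)
    # TSS identity: recall + TNR - 1
    expect_equal(unname(ms$per_class[cl, "tss"]),
                 unname(ms$per_class[cl, "recall"] + ms$per_class[cl, "tnr"] - 1),
                 tolerance = 1e-12)
    expect_equal(unname(ms$per_class[cl, "balanced_accuracy"]),
                 unname((ms$per_class[cl, "recall"] + ms$per_class[cl, "tnr"]) / 2),
                 tolerance = 1e-12)
  }
})

test_that("the two-stage model separates well-separated synthetic activities", {
  d <- make_separable()
  cfg <- activity_config("svm", n_components = 6, cost = 10, seed = 1)
  fit <- fit_activity_model(d$X, d$lab, d$rum, cfg)
  pred <- predict(fit, d$X)
  expect_equal(mean(pred$main_class == d$lab), 1)  # training accuracy 100%
  # determinism
  fit2 <- fit_activity_model(d$X, d$lab, d$rum, cfg)
  expect_identical(pred, predict(fit2, d$X))
  # refuse when a class is missing
  keep <- d$lab != "lying"
  expect_error(fit_activity_model(d$X[keep, ], d$lab[keep], d$rum[keep], cfg),
               "absent")
})

test_that("label-shuffled data scores at chance in cross-validation", {
  d <- make_separable(n_hours = 20, per_hour = 20)
  set.seed(53)
  shuffled <- sample(d$lab)
  folds <- cv_folds_by_hour(d$hour, k = 5, seed = 2)
  cfg <- activity_config("svm", n_components = 6, cost = 1, seed = 1)
  scores <- vapply(1:5, function(f) {
    tr <- folds != f
    fit <- fit_activity_model(d$X[tr, ], shuffled[tr], d$rum[tr], cfg)
    pred <- predict(fit, d$X[!tr, ])
    mean_balanced_accuracy(shuffled[!tr], pred$main_class)
  }, numeric(1))
  expect_equal(mean(scores), 0.5, tolerance = 0.05)  # 4-class chance level
})

test_that("standardization and projection never use held-out rows", {
  d <- make_separable()
  cfg <- activity_config("svm", n_components = 4, cost = 1, seed = 1)
  train <- d$hour <= 15
  fit1 <- fit_activity_model(d$X[train, ], d$lab[train], d$rum[train], cfg)
  # mutate the held-out rows wildly: fitted transforms must be unchanged
  X2 <- d$X
  X2[!train, ] <- X2[!train, ] * 100 + 7
  fit2 <- fit_activity_model(X2[train, ], d$lab[train], d$rum[train], cfg)
  expect_identical(fit1$projection, fit2$projection)
  expect_identical(predict(fit1, d$X[!train, ]), predict(fit2, d$X[!train, ]))
})

test_that("grid search scores every configuration and respects ties", {
  d <- make_separable(n_hours = 10, per_hour = 15)
  grid <- list(
    activity_config("svm", n_components = 2, cost = 1, seed = 1),
    activity_config("svm", n_components = 6, cost = 1, seed = 1)
  )
  gs <- grid_search_activity(d$X, d$lab, d$rum, d$hour, grid, k = 3, seed = 1)
  expect_equal(nrow(gs$report), 2)
  expect_true(gs$best_score >= max(gs$report$cv_mean_balanced_accuracy) - 1e-12)
  one <- grid_search_activity(d$X, d$lab, d$rum, d$hour, grid[1], k = 3, seed = 1)
  expect_identical(one$best, grid[[1]])
})
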