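# Quantifying environmental influence: regression of an environmental target
# on movement principal components, scored by the coefficient of
# determination on a session-held-out test set, with variation partitioning
# between the GPS and accelerometer families.

#' Split hourly records by pasture session
#'
#' @param records hourly records with a `session_id` column.
#' @param test_session session held out as the test set.
#' @param target optional target column name; when given, a warning is raised
#'   if the test-set target range is not contained in the train range
#'   (extrapolation risk).
#' @return List with integer row indices `train` and `test`.
#' @export
session_split <- function(records, test_session, target = NULL) {
  sessions <- unique(as.character(records$session_id))
  if (length(sessions) < 2L) stop("need at least 2 sessions to split")
  if (!test_session %in% sessions) {
    stop("unknown session: ", test_session)
  }
  test <- which(as.character(records$session_id) == test_session)
  train <- which(as.character(records$session_id) != test_session)
  if (!is.null(target)) {
    rtr <- range(records[[target]][train], na.rm = TRUE)
    rte <- range(records[[target]][test], na.rm = TRUE)
    if (rte[1] < rtr[1] || rte[2] > rtr[2]) {
      warning(sprintf(
        "test-set range of '%s' [%.3g, %.3g] extends beyond the train range [%.3g, %.3g]",
        target, rte[1], rte[2], rtr[1], rtr[2]
      ))
    }
  }
  list(train = train, test = test)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - f)^2) / sum((y - mean(y))^2)`, with the mean taken
#' over the observed (test) values. Interpreted as the fraction of
#' environmental variation traceable in the movement data; 0 is the
#' no-influence baseline of a learner that always predicts the mean, and
#' negative values (worse than the mean) are permitted.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return Value `<= 1`.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values have zero variance; R^2 undefined")
  1 - sum((observed - predicted)^2) / sst
}

#' Regressor configuration
#'
#' @param backend `"svr"` (kernel regression with epsilon-insensitive loss
#'   and a radial-basis kernel) or `"rfr"` (randomized tree ensemble,
#'   default 1000 trees).
#' @param n_components principal components used per included family.
#' @param cost,gamma,epsilon SVR hyperparameters (`gamma = NULL`: backend
#'   default `1/p`).
#' @param ntree tree count for `"rfr"`.
#' @param families character subset of `c("GPS", "ACC")`.
#' @param seed integer seed.
#' @return A list of class `regressor_config`.
#' @export
regressor_config <- function(backend = c("svr", "rfr"), n_components = 10L,
                             cost = 1, gamma = NULL, epsilon = 0.1,
                             ntree = 1000L, families = c("GPS", "ACC"),
                             seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(length(families) >= 1L, all(families %in% c("GPS", "ACC")))
  structure(list(backend = backend, n_components = as.integer(n_components),
                 cost = cost, gamma = gamma, epsilon = epsilon,
                 ntree = as.integer(ntree), families = families,
                 seed = as.integer(seed)),
            class = "regressor_config")
}

#' Fit a regressor and score it on held-out data
#'
#' @param X_train,X_test numeric matrices of movement principal components.
#' @param y_train,y_test numeric target vectors.
#' @param config a [regressor_config()].
#' @return List of class `influence_result`: `r2_test`, `observed`,
#'   `predicted`, `config`.
#' @export
fit_and_score <- function(X_train, y_train, X_test, y_test, config) {
  stopifnot(nrow(X_train) == length(y_train), nrow(X_test) == length(y_test))
  if (stats::sd(y_train) == 0) stop("degenerate (constant) training target")
  if (config$backend == "svr") {
    gamma <- if (is.null(config$gamma)) 1 / ncol(X_train) else config$gamma
    fit <- withr_seed(config$seed, e1071::svm(
      x = X_train, y = y_train, type = "eps-regression", kernel = "radial",
      cost = config$cost, gamma = gamma, epsilon = config$epsilon,
      scale = TRUE
    ))
  } else {
    fit <- withr_seed(config$seed, randomForest::randomForest(
      x = X_train, y = y_train, ntree = config$ntree
    ))
  }
  pred <- as.numeric(stats::predict(fit, X_test))
  structure(list(
    r2_test = r_squared(y_test, pred),
    observed = y_test, predicted = pred, config = config
  ), class = "influence_result")
}

#' Grid search for the environmental regressor
#'
#' Mode `"direct"` selects on the held-out test `R^2` itself — a pragmatic
#' shortcut when too few records remain for an inner validation set, but
#' optimistically biased and flagged as such in the output; mode `"nested"`
#' (default) selects on inner hour-blocked cross-validated `R^2` computed on
#' the training rows only. Ties break towards the fewest components, then
#' the smallest cost/tree count.
#'
#' @inheritParams fit_and_score
#' @param grid list of [regressor_config()] objects.
#' @param mode `"nested"` or `"direct"`.
#' @param hour_keys_train hour keys of the training rows (required for
#'   `"nested"`).
#' @param k inner folds for `"nested"` (default 5).
#' @param seed fold-assignment seed.
#' @return List with `best` config, `best_result` (an `influence_result` on
#'   the test set), `mode` and a per-config `report`.
#' @export
grid_search_regressor <- function(X_train, y_train, X_test, y_test, grid,
                                  mode = c("nested", "direct"),
                                  hour_keys_train = NULL, k = 5L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(grid) >= 1L)
  if (mode == "direct") {
    scores <- vapply(grid, function(cf) {
      fit_and_score(X_train, y_train, X_test, y_test, cf)$r2_test
    }, numeric(1))
  } else {
    if (is.null(hour_keys_train)) stop("'nested' mode requires hour_keys_train")
    folds <- cv_folds_by_hour(hour_keys_train, k, seed)
    scores <- vapply(grid, function(cf) {
      mean(vapply(seq_len(k), function(f) {
        tr <- folds != f
        if (stats::sd(y_train[tr]) == 0 || sum(!tr) < 2L) return(NA_real_)
        fit_and_score(X_train[tr, , drop = FALSE], y_train[tr],
                      X_train[!tr, , drop = FALSE], y_train[!tr], cf)$r2_test
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
  }
  complexity <- vapply(grid, function(cf) {
    cf$n_components * 1e6 + (if (cf$backend == "svr") cf$cost else cf$ntree)
  }, numeric(1))
  best <- order(-scores, complexity)[1]
  report <- data.frame(
    config = seq_along(grid),
    backend = vapply(grid, `[[`, character(1), "backend"),
    n_components = vapply(grid, `[[`, integer(1), "n_components"),
    selection_r2 = scores,
    mode = mode
  )
  list(best = grid[[best]],
       best_result = fit_and_score(X_train, y_train, X_test, y_test, grid[[best]]),
       mode = mode, report = report)
}

#' Partition explained variation between two sensor families
#'
#' Standard two-set variation partitioning from the three coefficients of
#' determination: `shared = R2_ACC + R2_GPS - R2_combined`,
#' `independent_ACC = R2_combined - R2_GPS`,
#' `independent_GPS = R2_combined - R2_ACC`. The identity
#' `shared + independent_ACC + independent_GPS = R2_combined` holds exactly;
#' negative components are reported as-is.
#'
#' @param r2_acc,r2_gps,r2_combined coefficients of determination of the
#'   accelerometer-only, GPS-only and combined models on the same
#'   target/split.
#' @return Named numeric vector with the three inputs and the three
#'   components.
#' @export
partition_variation <- function(r2_acc, r2_gps, r2_combined) {
  stopifnot(is.finite(r2_acc), is.finite(r2_gps), is.finite(r2_combined))
  c(
    r2_acc = r2_acc, r2_gps = r2_gps, r2_combined = r2_combined,
    shared = r2_acc + r2_gps - r2_combined,
    independent_acc = r2_combined - r2_gps,
    independent_gps = r2_combined - r2_acc
  )
}
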