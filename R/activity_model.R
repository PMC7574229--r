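# Two-stage activity classification from per-window movement features:
# stage 1 predicts the four mutually exclusive main activities, stage 2
# predicts rumination on standing/lying windows with a posture indicator.
# Splitting is blocked by clock hour throughout to respect the strong
# autocorrelation of movement data.

#' Hour-blocked train/test split
#'
#' Randomly assigns each distinct clock hour to the train or test partition;
#' no hour contributes rows to both.
#'
#' @param hour_keys integer hour identifier per row (see [hour_key()]).
#' @param test_fraction fraction of hours assigned to the test set
#'   (default 0.2).
#' @param seed integer seed controlling the assignment.
#' @return List with integer row indices `train` and `test`, and the
#'   underlying `test_hours`.
#' @export
hour_blocked_split <- function(hour_keys, test_fraction = 0.2, seed = 1L) {
  hours <- sort(unique(hour_keys))
  if (length(hours) < 2L) stop("need at least 2 distinct hours to split")
  n_test <- max(1L, round(test_fraction * length(hours)))
  if (n_test >= length(hours)) n_test <- length(hours) - 1L
  test_hours <- withr_seed(seed, sample(hours, n_test))
  list(
    train = which(!(hour_keys %in% test_hours)),
    test = which(hour_keys %in% test_hours),
    test_hours = test_hours
  )
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Hour-disjoint cross-validation folds
#'
#' @param hour_keys integer hour identifier per row.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return Integer fold id (1..k) per row; hours are distributed over folds
#'   in near-equal counts.
#' @export
cv_folds_by_hour <- function(hour_keys, k = 5L, seed = 1L) {
  hours <- sort(unique(hour_keys))
  if (length(hours) < k) stop("fewer distinct hours than folds")
  fold_of_hour <- withr_seed(seed, sample(rep_len(seq_len(k), length(hours))))
  fold_of_hour[match(hour_keys, hours)]
}

# Standardization + principal-component projection fitted on training rows
# only. Missing feature values are imputed as the (training) cell mean, i.e.
# 0 after z-scoring; zero-variance columns standardize to 0.
.fit_projection <- function(X, n_components) {
  mu <- colMeans(X, na.rm = TRUE)
  sg <- apply(X, 2L, stats::sd, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  sg[!is.finite(sg) | sg == 0] <- Inf  # constant/empty column -> all zeros
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, sg, "/")
  Z[!is.finite(Z)] <- 0
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$rotation))
  list(mu = mu, sg = sg, rotation = pc$rotation[, seq_len(nc), drop = FALSE],
       sdev = pc$sdev, n_components = nc)
}

.apply_projection <- function(proj, X) {
  Z <- sweep(sweep(X, 2L, proj$mu, "-"), 2L, proj$sg, "/")
  Z[!is.finite(Z)] <- 0
  Z %*% proj$rotation
}

#' Activity classifier configuration
#'
#' @param backend `"svm"` (radial-basis kernel, one-against-one multiclass)
#'   or `"rf"` (randomized tree ensemble).
#' @param n_components principal components retained as inputs.
#' @param cost,gamma,class_weights SVM hyperparameters (`gamma = NULL` uses
#'   the backend default `1/n_components`).
#' @param ntree,mtry,nodesize,sampsize random-forest hyperparameters
#'   (`NULL` = backend default; `ntree` default 500).
#' @param seed integer seed for the stochastic backends.
#' @return A list of class `activity_config`.
#' @export
activity_config <- function(backend = c("svm", "rf"), n_components = 10L,
                            cost = 1, gamma = NULL, class_weights = NULL,
                            ntree = 500L, mtry = NULL, nodesize = NULL,
                            sampsize = NULL, seed = 1L) {
  backend <- match.arg(backend)
  structure(list(backend = backend, n_components = as.integer(n_components),
                 cost = cost, gamma = gamma, class_weights = class_weights,
                 ntree = as.integer(ntree), mtry = mtry, nodesize = nodesize,
                 sampsize = sampsize, seed = as.integer(seed)),
            class = "activity_config")
}

.fit_backend_cls <- function(X, y, config) {
  y <- factor(y)
  if (config$backend == "svm") {
    gamma <- if (is.null(config$gamma)) 1 / ncol(X) else config$gamma
    withr_seed(config$seed, e1071::svm(
      x = X, y = y, kernel = "radial", cost = config$cost, gamma = gamma,
      class.weights = config$class_weights, scale = TRUE
    ))
  } else {
    args <- list(x = X, y = y, ntree = config$ntree)
    if (!is.null(config$mtry)) args$mtry <- config$mtry
    if (!is.null(config$nodesize)) args$nodesize <- config$nodesize
    if (!is.null(config$sampsize)) args$sampsize <- config$sampsize
    withr_seed(config$seed, do.call(randomForest::randomForest, args))
  }
}

#' Fit the two-stage activity model
#'
#' Standardization and the principal-component projection are fitted on the
#' training rows only. Stage 1 is a 4-class model of the main activity;
#' stage 2 is a binary rumination model over the standing/lying training
#' windows, taking the same projected features plus a posture indicator
#' (observed posture at training time, stage-1 predicted posture at
#' prediction time).
#'
#' @param features numeric matrix (rows = windows; accelerometer features
#'   plus the per-window individual GPS block).
#' @param main_class character/factor of the four main classes per row.
#' @param ruminating logical per row.
#' @param config an [activity_config()].
#' @return Object of class `activity_model`.
#' @export
fit_activity_model <- function(features, main_class, ruminating, config) {
  main_class <- as.character(main_class)
  classes <- c("grazing", "walking", "standing", "lying")
  missing_cls <- setdiff(classes, unique(main_class))
  if (length(missing_cls)) {
    stop("class(es) absent from training data: ",
         paste(missing_cls, collapse = ", "))
  }
  proj <- .fit_projection(features, config$n_components)
  P <- .apply_projection(proj, features)
  stage1 <- .fit_backend_cls(P, main_class, config)
  posture <- main_class %in% c("standing", "lying")
  stage2 <- NULL
  if (any(posture) && length(unique(ruminating[posture])) == 2L) {
    X2 <- cbind(P[posture, , drop = FALSE],
                standing = as.numeric(main_class[posture] == "standing"))
    stage2 <- .fit_backend_cls(X2, ifelse(ruminating[posture], "yes", "no"),
                               config)
  }
  structure(list(projection = proj, stage1 = stage1, stage2 = stage2,
                 config = config, classes = classes),
            class = "activity_model")
}

#' Predict activities for new windows
#'
#' @param object a fitted [fit_activity_model()] model.
#' @param features numeric feature matrix with the training columns.
#' @param ... unused.
#' @return Data frame with `main_class` and `ruminating` per row; rumination
#'   is only predicted on windows whose predicted posture is standing or
#'   lying, otherwise `FALSE`.
#' @export
predict.activity_model <- function(object, features, ...) {
  P <- .apply_projection(object$projection, features)
  main <- as.character(stats::predict(object$stage1, P))
  rum <- rep(FALSE, length(main))
  idx <- which(main %in% c("standing", "lying"))
  if (length(idx) && !is.null(object$stage2)) {
    X2 <- cbind(P[idx, , drop = FALSE],
                standing = as.numeric(main[idx] == "standing"))
    rum[idx] <- as.character(stats::predict(object$stage2, X2)) == "yes"
  }
  data.frame(main_class = main, ruminating = rum)
}

#' Grid search for the activity classifier
#'
#' Evaluates every configuration by hour-blocked k-fold cross-validated mean
#' balanced accuracy of the main-activity stage and returns the best. Ties
#' are broken towards the lowest-complexity configuration (fewest principal
#' components, then smallest cost/tree count).
#'
#' @param features,main_class,ruminating as in [fit_activity_model()].
#' @param hour_keys integer hour identifier per row.
#' @param grid list of [activity_config()] objects.
#' @param k folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return List with `best` (config), `best_score`, and `report` (data frame
#'   with one row per configuration).
#' @export
grid_search_activity <- function(features, main_class, ruminating, hour_keys,
                                 grid, k = 5L, seed = 1L) {
  stopifnot(length(grid) >= 1L)
  folds <- cv_folds_by_hour(hour_keys, k, seed)
  scores <- vapply(grid, function(cf) {
    fold_scores <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- fit_activity_model(features[tr, , drop = FALSE],
                                main_class[tr], ruminating[tr], cf)
      pred <- predict(fit, features[!tr, , drop = FALSE])
      mean_balanced_accuracy(main_class[!tr], pred$main_class)
    }, numeric(1))
    mean(fold_scores)
  }, numeric(1))
  complexity <- vapply(grid, function(cf) {
    cf$n_components * 1e6 + (if (cf$backend == "svm") cf$cost else cf$ntree)
  }, numeric(1))
  best <- order(-scores, complexity)[1]
  report <- data.frame(
    config = seq_along(grid),
    backend = vapply(grid, `[[`, character(1), "backend"),
    n_components = vapply(grid, `[[`, integer(1), "n_components"),
    cv_mean_balanced_accuracy = scores
  )
  list(best = grid[[best]], best_score = scores[best], report = report)
}
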