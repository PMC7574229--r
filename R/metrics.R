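# Classification performance metrics: mean balanced accuracy (the model
# selection criterion) and the full evaluation suite reported per class and
# macro-averaged.

#' Mean balanced accuracy
#'
#' One-versus-rest balanced accuracy per class,
#' `0.5 * (TP_x / P_x + TN_x / N_x)`, macro-averaged over classes.
#'
#' @param truth,predicted vectors of equal length (factors or characters).
#' @param classes class set; defaults to the classes present in `truth`.
#'   Every class must occur at least once in `truth`.
#' @return Value in \[0, 1\].
#' @export
mean_balanced_accuracy <- function(truth, predicted, classes = NULL) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(truth))
  P <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  if (any(P == 0)) {
    stop("class(es) with no positive instance in 'truth': ",
         paste(classes[P == 0], collapse = ", "))
  }
  ba <- vapply(classes, function(cl) {
    pos <- truth == cl
    tp <- sum(pos & predicted == cl)
    tn <- sum(!pos & predicted != cl)
    0.5 * (tp / sum(pos) + tn / sum(!pos))
  }, numeric(1))
  mean(ba)
}

#' Classification metric suite
#'
#' Overall accuracy, Cohen's kappa and the generalized (Gorodkin) multiclass
#' Matthews correlation coefficient, plus per-class and macro-averaged
#' balanced accuracy, true skill statistic, F1, precision, recall, negative
#' predictive value and true negative rate. Ratios with zero denominators are
#' reported as `NA`.
#'
#' @inheritParams mean_balanced_accuracy
#' @return List with elements `overall` (named vector: accuracy, kappa, mcc),
#'   `per_class` (matrix classes x 7 metrics) and `mean` (named vector of the
#'   7 macro-averages).
#' @export
metric_suite <- function(truth, predicted, classes = NULL) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  n <- length(truth)
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- unclass(cm)
  acc <- sum(diag(cm)) / n
  rs <- unname(rowSums(cm))  # true totals
  cs <- unname(colSums(cm))  # predicted totals
  pe <- sum(rs * cs) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else NA_real_
  # Gorodkin's generalization of the Matthews correlation coefficient
  num <- n * sum(diag(cm)) - sum(rs * cs)
  den <- sqrt(n^2 - sum(cs^2)) * sqrt(n^2 - sum(rs^2))
  mcc <- if (den > 0) num / den else NA_real_

  ratio <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  per <- t(vapply(classes, function(cl) {
    i <- match(cl, classes)
    tp <- cm[i, i]
    fn <- rs[i] - tp
    fp <- cs[i] - tp
    tn <- n - tp - fn - fp
    recall <- ratio(tp, tp + fn)
    tnr <- ratio(tn, tn + fp)
    precision <- ratio(tp, tp + fp)
    npv <- ratio(tn, tn + fn)
    f1 <- ratio(2 * tp, 2 * tp + fp + fn)
    c(balanced_accuracy = (recall + tnr) / 2,
      tss = recall + tnr - 1,
      f1 = f1, precision = precision, recall = recall, npv = npv, tnr = tnr)
  }, numeric(7)))
  rownames(per) <- classes
  list(
    overall = c(accuracy = acc, kappa = kappa, mcc = mcc),
    per_class = per,
    mean = colMeans(per)
  )
}
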