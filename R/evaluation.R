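#' Build a confusion matrix from scores
#'
#' Predicted positive means score >= \code{threshold} (default 0.5, stated
#' so confusion matrices are reproducible).
#'
#' @param y_true 0/1 truth vector.
#' @param y_score scores in \eqn{[0, 1]} (or hard 0/1 labels).
#' @param threshold decision cut (default 0.5).
#' @return A \code{"confusion"} object with counts \code{tp, fn, fp, tn}.
#' @export
confusion <- function(y_true, y_score, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_score), length(y_true) > 0)
  pred <- y_score >= threshold
  confusion_counts(tp = sum(pred & y_true == 1),
                   fn = sum(!pred & y_true == 1),
                   fp = sum(pred & y_true == 0),
                   tn = sum(!pred & y_true == 0))
}

#' Construct a confusion matrix from its four counts
#'
#' @param tp,fn,fp,tn nonnegative counts (total > 0).
#' @return A \code{"confusion"} object.
#' @examples
#' cm <- confusion_counts(tp = 876, fn = 124, fp = 161, tn = 839)
#' sensitivity(cm)  # 0.876
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn > 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(c("Actual Positive", "Actual Negative"),
                              c("Predicted Positive", "Predicted Negative")))
  print(m)
  invisible(x)
}

metric_ratio <- function(num, den, name) {
  if (den <= 0) {
    warning(name, " undefined (zero denominator); returning NA")
    return(NA_real_)
  }
  num / den
}

#' Confusion-matrix metrics
#'
#' The standard ratios: sensitivity \eqn{TP/(TP+FN)}, specificity
#' \eqn{TN/(TN+FP)}, accuracy \eqn{(TP+TN)/n}, precision \eqn{TP/(TP+FP)}
#' and F1 \eqn{2TP/(2TP+FP+FN)}. A zero denominator yields \code{NA} with a
#' warning rather than a silent 0, so fold averages are not deflated.
#'
#' @param cm a \code{"confusion"} object.
#' @return Numeric value in \eqn{[0, 1]} or \code{NA}.
#' @name cm_metrics
NULL

#' @rdname cm_metrics
#' @export
sensitivity <- function(cm) metric_ratio(cm$tp, cm$tp + cm$fn, "sensitivity")

#' @rdname cm_metrics
#' @export
specificity <- function(cm) metric_ratio(cm$tn, cm$tn + cm$fp, "specificity")

#' @rdname cm_metrics
#' @export
accuracy <- function(cm) {
  metric_ratio(cm$tp + cm$tn, cm$tp + cm$fn + cm$fp + cm$tn, "accuracy")
}

#' @rdname cm_metrics
#' @export
precision <- function(cm) metric_ratio(cm$tp, cm$tp + cm$fp, "precision")

#' @rdname cm_metrics
#' @export
f1_score <- function(cm) {
  metric_ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn, "f1")
}

#' Area under the ROC curve
#'
#' Computed through the tie-corrected rank (Mann–Whitney) statistic
#' \eqn{AUC = (R_1 - n_1(n_1+1)/2) / (n_1 n_0)} with midranks, which is
#' exactly the trapezoidal area when ties cross thresholds simultaneously.
#' Also returns the ROC curve points.
#'
#' @param y_true 0/1 truth with both classes present.
#' @param y_score numeric scores.
#' @return List: \code{auc}, and \code{curve} (data frame of fpr/tpr,
#'   descending thresholds).
#' @export
roc_auc <- function(y_true, y_score) {
  if (length(unique(y_true)) < 2L) stop("both classes required for ROC")
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  r <- rank(y_score)
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(y_score, decreasing = TRUE)
  ys <- y_true[ord]; ss <- y_score[ord]
  keep <- c(diff(ss) != 0, TRUE)  # collapse tied thresholds
  tpr <- cumsum(ys == 1)[keep] / n1
  fpr <- cumsum(ys == 0)[keep] / n0
  curve <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
                 data.frame(threshold = ss[keep], fpr = fpr, tpr = tpr))
  list(auc = auc, curve = curve)
}

#' Precision–recall curve and average precision
#'
#' Sweeps descending score thresholds and accumulates the step-interpolated
#' average precision \eqn{AP = \sum_k (R_k - R_{k-1}) P_k}.
#'
#' @param y_true 0/1 truth with at least one positive.
#' @param y_score numeric scores.
#' @return List: \code{average_precision}, and \code{curve} (recall,
#'   precision per threshold).
#' @export
pr_curve <- function(y_true, y_score) {
  n1 <- sum(y_true == 1)
  if (n1 == 0) stop("no positive cases")
  ord <- order(y_score, decreasing = TRUE)
  ys <- y_true[ord]; ss <- y_score[ord]
  tp <- cumsum(ys == 1)
  pp <- seq_along(ys)
  keep <- c(diff(ss) != 0, TRUE)
  rec <- tp[keep] / n1
  prec <- (tp / pp)[keep]
  ap <- sum(diff(c(0, rec)) * prec)
  list(average_precision = ap,
       curve = data.frame(threshold = ss[keep], recall = rec,
                          precision = prec))
}

#' Calibration (reliability) curve
#'
#' Bins scores into \code{bins} equal-width intervals on \eqn{[0, 1]} and
#' reports, per nonempty bin, the mean predicted probability and the
#' observed outcome frequency. A calibrated model lies on the diagonal.
#'
#' @param y_true 0/1 truth.
#' @param y_score probabilities in \eqn{[0, 1]}.
#' @param bins number of equal-width bins (default 10).
#' @return Data frame: \code{bin}, \code{n}, \code{mean_predicted},
#'   \code{observed_frequency}.
#' @export
calibration_curve <- function(y_true, y_score, bins = 10L) {
  stopifnot(all(y_score >= 0 & y_score <= 1))
  b <- pmin(pmax(ceiling(y_score * bins), 1L), bins)
  keep <- sort(unique(b))
  data.frame(
    bin = keep,
    n = vapply(keep, function(k) sum(b == k), numeric(1)),
    mean_predicted = vapply(keep, function(k) mean(y_score[b == k]),
                            numeric(1)),
    observed_frequency = vapply(keep, function(k) mean(y_true[b == k]),
                                numeric(1)))
}

#' Learning curve of a learner configuration
#'
#' For each training fraction, subsamples the cohort (stratified), runs
#' stratified k-fold cross-validation, and reports the mean training and
#' cross-validation accuracy. Infeasible fractions (too small for both
#' classes in every fold) are skipped with a warning.
#'
#' @param fit_fn function \code{cohort -> model} (model supports
#'   [predict_prob()]).
#' @param cohort a complete [cohort()].
#' @param fractions training-set fractions (default \code{seq(0.1, 1, 0.1)}).
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @return Data frame: \code{fraction}, \code{n}, \code{train_score},
#'   \code{cv_score}.
#' @export
learning_curve <- function(fit_fn, cohort, fractions = seq(0.1, 1, by = 0.1),
                           folds = 5L, seed = 1L) {
  rows <- lapply(seq_along(fractions), function(i) {
    fr <- fractions[i]
    n <- round(fr * nrow(cohort$x))
    sub <- try(stratified_subsample(cohort, n, seed = seed + i), silent = TRUE)
    if (inherits(sub, "try-error") || min(table(sub$y)) < folds) {
      warning("fraction ", fr, " infeasible; skipped")
      return(NULL)
    }
    fl <- kfold(sub, folds = folds, seed = seed + 1000L + i)
    sc <- vapply(fl, function(f) {
      m <- fit_fn(f$fit)
      c(train = mean((predict_prob(m, f$fit) >= 0.5) == (f$fit$y == 1L)),
        cv = mean((predict_prob(m, f$held) >= 0.5) == (f$held$y == 1L)))
    }, numeric(2))
    data.frame(fraction = fr, n = n,
               train_score = mean(sc["train", ]), cv_score = mean(sc["cv", ]))
  })
  do.call(rbind, rows)
}

#' Fold-averaged metric report for a learner configuration
#'
#' Runs stratified k-fold cross-validation of \code{fit_fn} on the cohort
#' and averages sensitivity, specificity, accuracy, precision, F1, ROC AUC
#' and average precision over the held-out folds.
#'
#' @param fit_fn function \code{cohort -> model}.
#' @param cohort a complete [cohort()].
#' @param folds CV folds (default 5).
#' @param threshold decision threshold (default 0.5).
#' @param seed integer seed.
#' @return One-row data frame of fold-averaged metrics.
#' @export
cv_metric_report <- function(fit_fn, cohort, folds = 5L, threshold = 0.5,
                             seed = 1L) {
  fl <- kfold(cohort, folds = folds, seed = seed)
  per <- vapply(fl, function(f) {
    m <- fit_fn(f$fit)
    p <- predict_prob(m, f$held)
    cm <- confusion(f$held$y, p, threshold)
    c(sensitivity = sensitivity(cm), specificity = specificity(cm),
      accuracy = accuracy(cm), precision = precision(cm), f1 = f1_score(cm),
      auc_roc = roc_auc(f$held$y, p)$auc,
      avg_precision = pr_curve(f$held$y, p)$average_precision)
  }, numeric(7))
  as.data.frame(t(rowMeans(per, na.rm = TRUE)))
}
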