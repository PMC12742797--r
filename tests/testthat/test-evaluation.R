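test_that("confusion counting matches a brute-force tally", {
  y <- c(1, 0, 1, 0)
  cm <- confusion(y, c(0.9, 0.1, 0.8, 0.2))
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(2, 0, 0, 2))

  # boundary rule: score equal to the threshold predicts positive
  cmb <- confusion(y, rep(0.5, 4), threshold = 0.5)
  expect_equal(c(cmb$tp, cmb$fp), c(2, 2))
  expect_equal(c(cmb$fn, cmb$tn), c(0, 0))

  set.seed(8)
  for (i in 1:20) {
    yt <- sample(c(0, 1), 50, replace = TRUE)
    ys <- runif(50)
    cm <- confusion(yt, ys, 0.4)
    expect_equal(cm$tp, sum(yt == 1 & ys >= 0.4))
    expect_equal(cm$fn, sum(yt == 1 & ys < 0.4))
    expect_equal(cm$fp, sum(yt == 0 & ys >= 0.4))
    expect_equal(cm$tn, sum(yt == 0 & ys < 0.4))
  }
  expect_error(confusion(numeric(0), numeric(0)))
})

test_that("metric ratios follow their count definitions", {
  cm <- confusion_counts(tp = 876, fn = 124, fp = 161, tn = 839)
  expect_equal(round(100 * sensitivity(cm), 1), 87.6)
  expect_equal(round(100 * specificity(cm), 1), 83.9)
  expect_equal(precision(cm), 876 / (876 + 161))
  expect_equal(f1_score(cm), 2 * 876 / (2 * 876 + 161 + 124))

  # zero denominators are missing, not zero
  none_pos <- confusion_counts(tp = 0, fn = 0, fp = 3, tn = 7)
  expect_warning(s <- sensitivity(none_pos), "sensitivity")
  expect_true(is.na(s))

  # algebraic identity: accuracy is the prevalence-weighted mean of
  # sensitivity and specificity
  set.seed(3)
  for (i in 1:10) {
    cnt <- sample(1:50, 4, replace = TRUE)
    cm <- confusion_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
    expect_equal(accuracy(cm),
                 (sensitivity(cm) * P + specificity(cm) * N) / (P + N))
    # both F1 forms agree
    expect_equal(f1_score(cm),
                 2 * precision(cm) * sensitivity(cm) /
                   (precision(cm) + sensitivity(cm)),
                 tolerance = 1e-12)
  }
})

test_that("ROC AUC equals the rank statistic and the trapezoidal area", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))$auc, 0)

  set.seed(5)
  y <- sample(c(0, 1), 300, replace = TRUE)
  s <- round(runif(300), 1)  # heavy ties
  r <- roc_auc(y, s)
  # trapezoidal area under the tie-collapsed curve as the oracle
  cv <- r$curve
  trap <- sum(diff(cv$fpr) * (cv$tpr[-1] + cv$tpr[-nrow(cv)]) / 2)
  expect_equal(r$auc, trap, tolerance = 1e-12)
  # and the Mann-Whitney U form via wilcox.test
  U <- unname(wilcox.test(s[y == 1], s[y == 0], exact = FALSE)$statistic)
  expect_equal(r$auc, U / (sum(y == 1) * sum(y == 0)), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(y, qlogis(pmin(pmax(s, 0.01), 0.99)))$auc, r$auc)
})

test_that("average precision follows the step-interpolated sweep", {
  expect_equal(pr_curve(c(0, 1, 1), c(0.1, 0.8, 0.9))$average_precision, 1)
  expect_error(pr_curve(c(0, 0), c(0.5, 0.6)), "positive")

  set.seed(6)
  y <- sample(c(0, 1), 400, replace = TRUE, prob = c(0.8, 0.2))
  s <- runif(400)
  ap <- pr_curve(y, s)$average_precision
  # null property: AP tends to prevalence
  expect_lt(abs(ap - mean(y)), 0.05)
  # brute-force threshold sweep oracle
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]; ss <- s[ord]
  rec_prev <- 0; ap_bf <- 0
  for (t in unique(ss)) {
    pred <- ss >= t
    rec <- sum(ys[pred]) / sum(y)
    prec <- sum(ys[pred]) / sum(pred)
    ap_bf <- ap_bf + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  expect_equal(ap, ap_bf, tolerance = 1e-12)
})

test_that("calibration curve bins scores and finds miscalibration", {
  y <- c(0, 1, 1, 0)
  cc <- calibration_curve(y, as.numeric(y))
  expect_equal(cc$mean_predicted, cc$observed_frequency)

  cc1 <- calibration_curve(c(0, 1), c(0.55, 0.52))
  expect_equal(nrow(cc1), 1)

  set.seed(7)
  s <- runif(20000)
  yb <- rbinom(20000, 1, s)
  ccb <- calibration_curve(yb, s)
  expect_lte(max(abs(ccb$mean_predicted - ccb$observed_frequency)), 0.05)
})

test_that("learning curves expose memorization and chance levels", {
  co <- generate_cohort(cohort_spec(n = 400, prevalence = 0.3, seed = 71))
  memorizer <- function(tr) fit_cart(tr, max_depth = 50, min_leaf = 1)
  lc <- learning_curve(memorizer, co, fractions = c(0.5, 1.0), folds = 3,
                       seed = 2)
  expect_true(all(lc$train_score == 1.0))

  null_co <- generate_cohort(cohort_spec(n = 800, prevalence = 0.3,
                                         effect_sizes = 0, seed = 72))
  lcn <- learning_curve(function(tr) fit_cart(tr, max_depth = 3), null_co,
                        fractions = 1.0, folds = 5, seed = 3)
  expect_lte(abs(lcn$cv_score - max(mean(null_co$y), 1 - mean(null_co$y))),
             0.03 + 1e-9)

  # fraction 1.0 equals plain cross-validation
  plain <- cv_metric_report(function(tr) fit_cart(tr, max_depth = 3),
                            null_co, folds = 5, seed = 1003 + 1)
  lc1 <- learning_curve(function(tr) fit_cart(tr, max_depth = 3), null_co,
                        fractions = 1.0, folds = 5, seed = 3)
  expect_equal(lc1$cv_score, plain$accuracy, tolerance = 1e-12)
})
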