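test_that("AdaBoost round computes the weighted error and weight update", {
  # two coincident points with contradictory labels force eps = w(minority)
  co <- mat_cohort(cbind(f1 = c(1, 1), f2 = c(0, 0)), c(1L, 0L))
  r <- adaboost_round(co, w = c(0.9, 0.1))
  expect_equal(r$eps, 0.1)
  expect_equal(r$alpha, 0.5 * log(9))  # ~1.0986
  expect_false(r$rejected)
  # the misclassified point's weight strictly increases
  expect_gt(r$w_next[2], 0.1)
  expect_lt(r$w_next[1], 0.9)
  expect_equal(sum(r$w_next), 1)

  # balanced contradictory labels: eps = 0.5, round rejected with alpha 0
  co2 <- mat_cohort(cbind(f1 = c(1, 1), f2 = c(0, 0)), c(1L, 0L))
  r2 <- adaboost_round(co2, w = c(0.5, 0.5))
  expect_equal(r2$eps, 0.5)
  expect_equal(r2$alpha, 0)
  expect_true(r2$rejected)

  # a perfect stump hits the capped alpha
  co3 <- mat_cohort(cbind(f1 = c(-1, 1), f2 = c(0, 0)), c(0L, 1L))
  r3 <- adaboost_round(co3, w = c(0.5, 0.5))
  expect_equal(r3$eps, 0)
  expect_equal(r3$alpha, 0.5 * log((1 - 1e-10) / 1e-10))
})

test_that("AdaBoost training error obeys the exponential-loss bound", {
  co <- generate_cohort(cohort_spec(n = 200, prevalence = 0.4, seed = 51))
  m <- fit_adaboost(co, rounds = 20, seed = 3)
  expect_true(all(m$epsilons < 0.5))
  bound <- prod(2 * sqrt(m$epsilons * (1 - m$epsilons)))
  train_err <- mean((predict_prob(m, co) >= 0.5) != (co$y == 1))
  expect_lte(train_err, bound + 1e-12)
  # bound shrinks as informative rounds accumulate
  expect_lt(bound, 1)
})

test_that("bagging draws bootstraps and votes", {
  co <- separable_cohort(120, seed = 7)
  b1 <- fit_bagging(co, B = 1, seed = 9)
  base <- fit_cart(cohort_rows(co, b1$bootstrap_rows[[1]]))
  expect_equal(predict_prob(b1, co), as.numeric(predict_prob(base, co) >= 0.5))

  # rows on which every learner agrees get vote share exactly 0 or 1
  b <- fit_bagging(co, B = 7, seed = 5)
  votes <- sapply(b$models, function(m) predict_prob(m, co) >= 0.5)
  unanimous <- rowSums(votes) %in% c(0, 7)
  expect_gt(mean(unanimous), 0.5)
  p <- predict_prob(b, co)
  expect_true(all(p[unanimous] %in% c(0, 1)))

  big <- fit_bagging(separable_cohort(5000, seed = 1), B = 3, seed = 2)
  uf <- sapply(big$bootstrap_rows, function(r) length(unique(r)) / 5000)
  expect_true(all(abs(uf - (1 - exp(-1))) < 0.03))
})

test_that("majority vote is the mode with the stated tie-breaks", {
  expect_identical(majority_vote(c(1L, 1L, 0L)), 1L)
  expect_identical(majority_vote(c(1L, 0L), probs = c(0.9, 0.3)), 1L)
  expect_identical(majority_vote(c(1L, 0L), probs = c(0.6, 0.4)), 1L)
  expect_identical(majority_vote(c(1L, 0L), probs = c(0.7, 0.1)), 0L)
  expect_identical(majority_vote(c(1L, 0L), probs = c(0.6, 0.4)), 1L)
  expect_identical(majority_vote(c(1L, 0L)), 1L)  # residual tie -> positive
  set.seed(4)
  for (i in 1:50) {
    votes <- sample(c(0L, 1L), 5, replace = TRUE)
    expect_identical(majority_vote(votes),
                     as.integer(sum(votes) > 2.5))
  }
})

test_that("probability averaging is the arithmetic mean", {
  expect_equal(average_probs(c(0.3, 0.3, 0.3)), 0.3)
  expect_equal(average_probs(c(0, 1)), 0.5)
  set.seed(2)
  p <- matrix(runif(30), 10, 3)
  expect_equal(average_probs(p), rowMeans(p))
  models <- list(fixed_prob_model(0.2), fixed_prob_model(0.6))
  vt <- fit_voting(models)
  expect_equal(predict_prob(vt, matrix(0, 4, 1)), rep(0.4, 4))
})

test_that("stacking learns meta-weights on the hold-out only", {
  co <- generate_cohort(cohort_spec(n = 600, prevalence = 0.3, seed = 61))
  sp <- split_cohort(co, seed = 3)
  bases <- list(fit_cart(sp$train), fit_anrdt(sp$train, sp$val))
  st <- fit_stacking(bases, sp$val)
  expect_equal(ncol(st$Z), 2)
  expect_equal(nrow(st$Z), nrow(sp$val$x))  # built from val rows only
  p <- predict_prob(st, sp$test)
  expect_true(all(p >= 0 & p <= 1))

  # one perfect base among noise learners gets the largest meta weight
  perfect <- structure(list(truth = sp$val$y), class = "oracleprob")
  registerS3method("predict_prob", "oracleprob",
                   function(model, x) {
                     n <- nrow(if (inherits(x, "cohort")) x$x else x)
                     # emits the stored labels (only meaningful on val)
                     p <- rep(0.5, n)
                     if (n == length(model$truth)) {
                       p <- 0.02 + 0.96 * model$truth
                     }
                     p
                   },
                   envir = asNamespace("chdrisk"))
  noise1 <- fixed_prob_model(0.52)
  noise2 <- fixed_prob_model(0.48)
  st2 <- fit_stacking(list(noise1, perfect, noise2), sp$val)
  w <- st2$coef[-1]
  expect_equal(which.max(abs(w)), 2L)
  expect_gt(w[2], 0)
})

test_that("degenerate single-base stacking reduces to calibration", {
  co <- generate_cohort(cohort_spec(n = 500, prevalence = 0.3, seed = 63))
  sp <- split_cohort(co, seed = 1)
  base <- fit_cart(sp$train)
  st <- fit_stacking(list(base), sp$val)
  pb <- predict_prob(base, sp$val)
  cal <- glm(sp$val$y ~ pb, family = binomial())
  p_cal <- unname(fitted(cal))
  p_st <- predict_prob(st, sp$val)
  expect_lt(abs(chdrisk:::log_loss(sp$val$y, p_st) -
                  chdrisk:::log_loss(sp$val$y, p_cal)), 1e-6)
})

test_that("BMA posterior weights normalise, order-invariantly", {
  val <- mat_cohort(cbind(f1 = c(0, 0), f2 = c(0, 0)), c(1L, 0L))
  same <- list(fixed_prob_model(0.6), fixed_prob_model(0.6),
               fixed_prob_model(0.6))
  bm <- fit_bma(same, val)
  expect_equal(bm$weights, rep(1 / 3, 3))

  # one-row validation with likelihood gap exactly ln 4 -> weights 4:1
  val1 <- mat_cohort(cbind(f1 = c(0, 1), f2 = c(0, 0)), c(1L, 1L))
  a <- fixed_prob_model(0.8)
  b <- fixed_prob_model(0.2)
  # per-row likelihood gap ln(0.8/0.2) = ln 4, so the posterior ratio is
  # exp(gap): two rows give 2 ln 4 and ratio 16
  bm2 <- fit_bma(list(a, b), val1)
  expect_equal(bm2$weights[1] / bm2$weights[2], 16)
  expect_equal(sum(bm2$weights), 1, tolerance = 1e-12)
  bm2r <- fit_bma(list(b, a), val1)
  expect_equal(bm2r$weights, rev(bm2$weights))

  # overconfident zero-probability candidates are floored, not -Inf
  z <- fixed_prob_model(0)
  bm3 <- fit_bma(list(z, a), val1)
  expect_equal(sum(bm3$weights), 1, tolerance = 1e-12)
  expect_gt(bm3$weights[2], 0.999)
})

test_that("BMA prediction is the posterior-weighted mixture", {
  val <- mat_cohort(cbind(f1 = c(0, 1), f2 = c(1, 0)), c(1L, 0L))
  models <- list(fixed_prob_model(0.9), fixed_prob_model(0.1))
  bm <- fit_bma(models, val)
  p <- predict_prob(bm, matrix(0, 3, 2))
  expect_equal(p, rep(sum(bm$weights * c(0.9, 0.1)), 3))
})
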