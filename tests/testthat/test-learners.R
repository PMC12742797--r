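test_that("soft gate follows the sigmoid and its hard limit", {
  expect_equal(soft_gate(3, 3, 1), 0.5)
  expect_equal(soft_gate(log(3), 0, 1), 0.25)  # 1/(1+3)
  expect_equal(soft_gate(5, 0, Inf), 0)
  expect_equal(soft_gate(-5, 0, Inf), 1)
  expect_equal(soft_gate(0, 0, Inf), 1)  # x <= theta routes left
  expect_equal(soft_gate(1000, 0, 50), 0)  # no overflow
})

test_that("soft tree prediction equals explicit path enumeration", {
  co <- threshold_cohort(300, seed = 2)
  fit <- fit_anrdt(co, max_depth = 3, min_leaf = 5, beta0 = 4)

  enumerate_paths <- function(node, x, p_path = 1) {
    if (node$leaf) return(p_path * node$prob[2])
    g <- soft_gate(x[node$feature], node$theta, node$beta)
    enumerate_paths(node$left, x, p_path * g) +
      enumerate_paths(node$right, x, p_path * (1 - g))
  }
  set.seed(3)
  xs <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(predict_prob(fit, xs),
               apply(xs, 1, enumerate_paths, node = fit$tree))
  # leaf path probabilities always mix to a proper probability
  p0 <- 1 - predict_prob(fit, xs)
  expect_true(all(p0 >= 0 & p0 <= 1))
})

test_that("infinite steepness reproduces the hard CART exactly", {
  co <- generate_cohort(cohort_spec(n = 200, prevalence = 0.3, seed = 17))
  sp <- split_cohort(co, seed = 1)
  hard <- fit_cart(sp$train, max_depth = 5, min_leaf = 5)
  soft_inf <- fit_anrdt(sp$train, val = NULL, max_depth = 5, min_leaf = 5,
                        beta0 = Inf)
  p_hard <- predict_prob(hard, sp$test)
  p_soft <- predict_prob(soft_inf, sp$test)
  expect_identical(as.integer(p_soft >= 0.5), as.integer(p_hard >= 0.5))
  expect_equal(p_soft, p_hard)
})

test_that("a pure single-split dataset yields a perfect depth-1 tree", {
  co <- threshold_cohort(100, seed = 5)
  fit <- fit_anrdt(co, val = co, max_depth = 4, min_leaf = 1, beta0 = 50)
  expect_lte(chdrisk:::tree_depth(fit$tree), 4)
  acc <- mean((predict_prob(fit, co) >= 0.5) == (co$y == 1))
  expect_equal(acc, 1.0)
  hard <- fit_cart(co, max_depth = 4, min_leaf = 1)
  expect_equal(chdrisk:::tree_depth(hard$tree), 1)
})

test_that("soft splits resist label noise at least as well as hard CART", {
  wins <- 0
  for (rep in 1:10) {
    co <- generate_cohort(cohort_spec(n = 400, prevalence = 0.35,
                                      seed = 100 + rep))
    sp <- split_cohort(co, seed = rep)
    tr <- sp$train
    set.seed(rep)
    flip <- sample(nrow(tr$x), round(0.1 * nrow(tr$x)))
    tr$y[flip] <- 1L - tr$y[flip]
    soft <- fit_anrdt(tr, sp$val, max_depth = 6, min_leaf = 10, beta0 = 4)
    hard <- fit_cart(tr, max_depth = 6, min_leaf = 10)
    ll <- function(m) chdrisk:::log_loss(sp$test$y, predict_prob(m, sp$test))
    if (ll(soft) <= ll(hard)) wins <- wins + 1
  }
  expect_gte(wins, 7)
})

test_that("HIRF weights are a normalized contribution score", {
  co <- threshold_cohort(200, seed = 7)
  val <- threshold_cohort(100, seed = 8)
  # perfect stumps vs a coin-flip leaf: the uninformative tree gets the
  # strictly smallest weight
  trees <- list(stump_node(1, 0, 0.05, 0.95),
                stump_node(1, 0, 0.1, 0.9),
                leaf_node(0.5))
  w <- hirf_tree_weights(trees, val)
  expect_equal(sum(w), 1, tolerance = 1e-10)
  expect_true(all(w >= 0))
  expect_equal(which.min(w), 3L)
  expect_equal(w[3], 0)
  # identical trees share the weight uniformly (symmetry)
  w_same <- hirf_tree_weights(list(trees[[1]], trees[[1]], trees[[1]]), val)
  expect_equal(w_same, rep(1 / 3, 3))
  # weights are permutation-equivariant in tree order
  w_perm <- hirf_tree_weights(trees[c(3, 1, 2)], val)
  expect_equal(w_perm, w[c(3, 1, 2)])

  fit <- fit_hirf(co, val, n_trees = 15, smote_k = 3, seed = 5)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
  expect_true(all(fit$weights >= 0))
})

test_that("HIRF prediction is the weighted tree mixture", {
  trees <- list(stump_node(1, 0, 0.2, 0.8),
                stump_node(2, 1, 0.3, 0.7),
                leaf_node(0.5))
  x <- matrix(c(-1, 0.5, 2, 3), 2, 2, dimnames = list(NULL, c("f1", "f2")))
  per_tree <- cbind(c(0.2, 0.8), c(0.7, 0.7), c(0.5, 0.5))
  w <- c(0.5, 0.3, 0.2)
  model <- structure(list(trees = trees, weights = w,
                          features = c("f1", "f2")), class = "hirf")
  expect_equal(predict_prob(model, x), drop(per_tree %*% w))
  # degenerate weights pick out single trees
  model$weights <- c(1, 0, 0)
  expect_equal(predict_prob(model, x), per_tree[, 1])
  model$weights <- rep(1 / 3, 3)
  expect_equal(predict_prob(model, x), rowMeans(per_tree))
})

test_that("HIRF falls back to uniform weights on a degenerate validation set", {
  co <- threshold_cohort(120, seed = 9)
  val1 <- cohort_rows(co, which(co$y == 1))
  expect_warning(fit <- fit_hirf(co, val1, n_trees = 5, smote_k = 3,
                                 seed = 2), "uniform")
  expect_equal(fit$weights, rep(0.2, 5))
})

test_that("Huber loss has the stated piecewise form and bounded gradient", {
  expect_equal(huber_loss(0, 0), 0)
  expect_equal(huber_loss(2, 0, delta = 1), 1.5)  # delta*(|r| - delta/2)
  r <- 0.37
  expect_equal(huber_loss(r, 0, delta = 1e6), r^2 / 2)
  # continuity and once-differentiability at |r| = delta
  d <- 1.3
  expect_equal(huber_loss(d - 1e-9, 0, d), huber_loss(d + 1e-9, 0, d),
               tolerance = 1e-6)
  # convex in yhat: midpoint below chord on a grid
  yh <- seq(-4, 4, 0.25)
  L <- huber_loss(1, yh, delta = 1)
  expect_true(all(L[-c(1, length(L))] <= (L[-c(1, 2)] + L[1:(length(L) - 2)]) / 2 + 1e-12))
  expect_true(all(abs(chdrisk:::huber_gradient(seq(-10, 10, 0.5), d)) <= d))
})

test_that("gradient boosting starts at the prior and learns separable data", {
  co <- separable_cohort(150, gap = 2, seed = 3)
  # lr = 0: constant model at the prior
  m0 <- fit_gradient_boost(co, loss = "logistic", learning_rate = 0,
                           max_rounds = 3)
  expect_equal(predict_prob(m0, co), rep(mean(co$y), 150))
  m0h <- fit_gradient_boost(co, loss = "huber", learning_rate = 0,
                            max_rounds = 3)
  expect_equal(predict_prob(m0h, co), rep(mean(co$y), 150))

  # separable toy reaches training accuracy 1 within 50 rounds
  m <- fit_pgbm(co, val = co, max_rounds = 50, learning_rate = 0.3,
                patience = 50)
  acc <- mean((predict_prob(m, co) >= 0.5) == (co$y == 1))
  expect_equal(acc, 1.0)
})

test_that("training logistic loss is nonincreasing over rounds", {
  co <- generate_cohort(cohort_spec(n = 300, prevalence = 0.3, seed = 23))
  m <- fit_gradient_boost(co, loss = "logistic", learning_rate = 0.1,
                          max_rounds = 50)
  losses <- vapply(0:50, function(k) {
    mk <- m; mk$trees <- m$trees[seq_len(k)]
    chdrisk:::log_loss(co$y, predict_prob(mk, co))
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-8))
})

test_that("early stopping halts on noise and keeps the best round", {
  set.seed(31)
  co <- mat_cohort(matrix(rnorm(200 * 3), 200, 3),
                   sample(c(0L, 1L), 200, replace = TRUE))
  val <- mat_cohort(matrix(rnorm(100 * 3), 100, 3),
                    sample(c(0L, 1L), 100, replace = TRUE))
  m <- fit_pgbm(co, val, patience = 1, max_rounds = 100,
                learning_rate = 0.3)
  expect_lt(m$rounds_run, 100)
  # retained round has the minimum validation loss seen
  expect_equal(m$val_losses[m$rounds_used + 1], min(m$val_losses))
})

test_that("one full-depth unit-rate round drives training error to zero", {
  co <- separable_cohort(80, gap = 1.5, seed = 11)  # balanced, duplicate-free
  m <- fit_gradient_boost(co, loss = "logistic", learning_rate = 1,
                          max_rounds = 1, max_depth = 30, min_leaf = 1)
  expect_equal(mean((predict_prob(m, co) >= 0.5) == (co$y == 1)), 1.0)
})
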