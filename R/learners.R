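#' Positive-class probability of a fitted model
#'
#' Common prediction surface for every learner and ensemble in the package.
#'
#' @param model a fitted model object.
#' @param x numeric feature matrix (columns in training order) or a
#'   [cohort()].
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_prob <- function(model, x) UseMethod("predict_prob")

feature_matrix <- function(x) {
  if (inherits(x, "cohort")) x$x else as.matrix(x)
}

#' Fit a hard classification tree (baseline CART configuration)
#'
#' The reference decision tree: greedy Gini splits, hard thresholds, no
#' softening. The same growth engine underlies [fit_anrdt()], so their
#' comparison isolates the effect of sigmoid gating.
#'
#' @param train a complete [cohort()].
#' @param max_depth,min_leaf growth limits.
#' @return A \code{"cart"} model.
#' @export
fit_cart <- function(train, max_depth = 6L, min_leaf = 10L) {
  if (length(unique(train$y)) < 2L) stop("training data has a single class")
  structure(list(tree = grow_tree(train$x, train$y, type = "class",
                                  max_depth = max_depth, min_leaf = min_leaf),
                 features = colnames(train$x)),
            class = "cart")
}

#' @export
predict_prob.cart <- function(model, x) {
  predict_tree_hard(model$tree, feature_matrix(x), "prob")
}

#' Fit an adaptive noise-resistant decision tree (soft-split tree)
#'
#' Grows a hard Gini tree, then replaces each hard threshold with a sigmoid
#' gate \eqn{f(x) = 1/(1 + e^{\beta (x - \theta)})} whose steepness is
#' \eqn{\beta = \beta_0 / s_j} for the split feature's training standard
#' deviation \eqn{s_j}, so decisions blur over a fixed fraction of each
#' feature's natural spread. The tree is cost-complexity pruned against
#' validation log-loss of the softened predictions. With
#' \code{beta0 = Inf} the model reproduces the hard CART exactly.
#'
#' @param train,val complete [cohort()]s; \code{val} may be \code{NULL} to
#'   skip pruning.
#' @param max_depth,min_leaf growth limits.
#' @param beta0 dimensionless gate steepness (default 4).
#' @return An \code{"anrdt"} model.
#' @export
fit_anrdt <- function(train, val = NULL, max_depth = 6L, min_leaf = 10L,
                      beta0 = 4) {
  if (length(unique(train$y)) < 2L) stop("training data has a single class")
  sds <- apply(train$x, 2, stats::sd)
  hard <- grow_tree(train$x, train$y, type = "class",
                    max_depth = max_depth, min_leaf = min_leaf)
  cands <- if (!is.null(val)) prune_sequence(hard) else list(hard)
  soft <- lapply(cands, soften_tree, feature_sd = sds, beta0 = beta0)
  pick <- 1L
  if (!is.null(val) && length(soft) > 1L) {
    losses <- vapply(soft, function(tr)
      log_loss(val$y, predict_tree_soft_matrix(tr, val$x)), numeric(1))
    pick <- which.min(losses)
  }
  structure(list(tree = soft[[pick]], beta0 = beta0, feature_sd = sds,
                 features = colnames(train$x)),
            class = "anrdt")
}

#' @export
predict_prob.anrdt <- function(model, x) {
  predict_tree_soft_matrix(model$tree, feature_matrix(x))
}

#' Fit a hybrid imbalanced random forest
#'
#' A random forest in which every tree is trained on a SMOTE-balanced
#' bootstrap (so each tree sees a 50/50 class mix) with \eqn{\sqrt d}
#' feature subsampling per split, and trees are combined with nonuniform
#' weights \eqn{\hat y = \sum_i w_i T_i(x)}. Each tree's weight is its mean
#' contribution toward the correct class on the validation set — the
#' probability it assigns to the true label minus 0.5, clipped at zero —
#' normalised to sum to one. A degenerate (single-class) validation set
#' falls back to uniform weights with a warning.
#'
#' @param train,val complete [cohort()]s.
#' @param n_trees number of trees (default 200).
#' @param smote_k,smote_ratio SMOTE parameters for the per-bootstrap balance.
#' @param max_depth,min_leaf tree growth limits.
#' @param seed integer seed.
#' @return A \code{"hirf"} model with components \code{trees} and
#'   \code{weights} (nonnegative, summing to 1).
#' @export
fit_hirf <- function(train, val = NULL, n_trees = 200L, smote_k = 5L,
                     smote_ratio = 1, max_depth = 8L, min_leaf = 5L,
                     seed = 2025L) {
  if (length(unique(train$y)) < 2L) stop("training data has a single class")
  d <- ncol(train$x)
  mtry <- max(1L, floor(sqrt(d)))
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(b) {
      rows <- sample.int(nrow(train$x), replace = TRUE)
      boot <- cohort_rows(train, rows)
      n_min <- min(table(boot$y))
      if (length(unique(boot$y)) == 2L && n_min > smote_k) {
        boot <- smote_balance(boot, k = smote_k, target_ratio = smote_ratio,
                              seed = sample.int(.Machine$integer.max, 1))
      }
      grow_tree(boot$x, boot$y, type = "class", max_depth = max_depth,
                min_leaf = min_leaf, mtry = mtry)
    })
  })
  w <- rep(1 / n_trees, n_trees)
  if (!is.null(val) && length(unique(val$y)) == 2L) {
    w <- hirf_tree_weights(trees, val)
  } else if (!is.null(val)) {
    warning("single-class validation set; HIRF falls back to uniform weights")
  }
  structure(list(trees = trees, weights = w, features = colnames(train$x)),
            class = "hirf")
}

#' Contribution weights for a set of trees
#'
#' The tree-level contribution score behind the weighted forest: each
#' tree's mean signed vote toward the true class on the validation rows —
#' the probability it assigns to the observed label minus 0.5, clipped at
#' zero — normalised to sum to one. If every tree scores zero the weights
#' fall back to uniform.
#'
#' @param trees list of fitted classification trees (internal node lists).
#' @param val a complete [cohort()] with both classes.
#' @return Nonnegative weights summing to 1, one per tree.
#' @export
hirf_tree_weights <- function(trees, val) {
  contrib <- vapply(trees, function(tr) {
    p <- predict_tree_hard(tr, val$x, "prob")
    p_true <- ifelse(val$y == 1L, p, 1 - p)
    mean(pmax(p_true - 0.5, 0))
  }, numeric(1))
  if (sum(contrib) > 0) contrib / sum(contrib) else
    rep(1 / length(trees), length(trees))
}

#' @export
predict_prob.hirf <- function(model, x) {
  xm <- feature_matrix(x)
  preds <- vapply(model$trees, predict_tree_hard, numeric(nrow(xm)), x = xm,
                  what = "prob")
  if (nrow(xm) == 1L) preds <- matrix(preds, nrow = 1L)
  drop(preds %*% model$weights)
}

#' Huber loss
#'
#' \eqn{L(y, \hat y) = \tfrac12 (y - \hat y)^2} when
#' \eqn{|y - \hat y| \le \delta}, and
#' \eqn{\delta (|y - \hat y| - \delta/2)} otherwise: quadratic near the
#' target, linear in the tails, continuous and once-differentiable at
#' \eqn{|r| = \delta}, so single gross residuals cannot dominate the fit.
#'
#' @param y,yhat numeric vectors.
#' @param delta outlier threshold (> 0, default 1).
#' @return Elementwise loss values.
#' @examples
#' huber_loss(2, 0, delta = 1)  # 1.5
#' @export
huber_loss <- function(y, yhat, delta = 1) {
  stopifnot(delta > 0)
  r <- abs(y - yhat)
  ifelse(r <= delta, 0.5 * r^2, delta * (r - delta / 2))
}

huber_gradient <- function(r, delta) {
  # derivative of huber_loss wrt yhat is -psi(r); psi is the clipped residual
  pmin(pmax(r, -delta), delta)
}

#' Stagewise gradient boosting
#'
#' Builds the additive model \eqn{F_m(x) = F_{m-1}(x) + \alpha\, h_m(x)} by
#' fitting a depth-limited regression tree to the negative loss gradient at
#' each round. \code{loss = "logistic"} boosts the binomial deviance on the
#' log-odds scale (the plain GBM baseline); \code{loss = "huber"} boosts the
#' Huber loss of the margin residual \eqn{y^{\pm} - F(x)} (labels encoded
#' \eqn{\pm 1}, probabilities read off as \code{plogis(2 F)}), which damps
#' the influence of mislabeled points. With a validation cohort the fit
#' stops once validation log-loss has not improved for \code{patience}
#' rounds and the best round is retained.
#'
#' @param train,val complete [cohort()]s (\code{val} optional).
#' @param loss \code{"logistic"} or \code{"huber"}.
#' @param learning_rate step size (default 0.1).
#' @param max_rounds maximum boosting rounds (>= 1).
#' @param patience early-stop rounds without improvement (default Inf).
#' @param max_depth,min_leaf base-tree limits (default depth 3).
#' @param delta Huber threshold (default 1).
#' @return A \code{"gboost"} model; \code{$rounds_used} records where early
#'   stopping retained the fit.
#' @export
fit_gradient_boost <- function(train, val = NULL,
                               loss = c("logistic", "huber"),
                               learning_rate = 0.1, max_rounds = 100L,
                               patience = Inf, max_depth = 3L, min_leaf = 10L,
                               delta = 1) {
  loss <- match.arg(loss)
  if (max_rounds < 1L) stop("max_rounds must be at least 1")
  if (length(unique(train$y)) < 2L) stop("training data has a single class")
  y <- train$y
  p1 <- mean(y)
  # logistic: F is the log-odds; huber: F is half-log-odds (margin scale)
  f0 <- if (loss == "logistic") stats::qlogis(p1) else 0.5 * stats::qlogis(p1)
  to_prob <- function(f) if (loss == "logistic") stats::plogis(f) else
    stats::plogis(2 * f)
  fx <- rep(f0, length(y))
  fv <- if (!is.null(val)) rep(f0, nrow(val$x)) else NULL
  trees <- list()
  best <- list(loss = if (!is.null(val)) log_loss(val$y, to_prob(fv)) else Inf,
               round = 0L)
  stall <- 0L
  val_losses <- if (!is.null(val)) best$loss else numeric(0)
  for (m in seq_len(max_rounds)) {
    g <- if (loss == "logistic") y - stats::plogis(fx) else
      huber_gradient((2 * y - 1) - fx, delta)
    if (learning_rate == 0) break  # constant model at the prior
    tr <- grow_tree(train$x, g, type = "reg", max_depth = max_depth,
                    min_leaf = min_leaf)
    trees[[m]] <- tr
    fx <- fx + learning_rate * predict_tree_hard(tr, train$x, "value")
    if (!is.null(val)) {
      fv <- fv + learning_rate * predict_tree_hard(tr, val$x, "value")
    }
    if (!is.null(val)) {
      vl <- log_loss(val$y, to_prob(fv))
      val_losses <- c(val_losses, vl)
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, round = m); stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    } else {
      best$round <- m
    }
  }
  structure(list(f0 = f0, trees = trees[seq_len(best$round)],
                 learning_rate = learning_rate, loss = loss, delta = delta,
                 rounds_used = best$round, rounds_run = length(trees),
                 val_losses = val_losses, features = colnames(train$x)),
            class = "gboost")
}

#' @export
predict_prob.gboost <- function(model, x) {
  xm <- feature_matrix(x)
  f <- rep(model$f0, nrow(xm))
  for (tr in model$trees) {
    f <- f + model$learning_rate * predict_tree_hard(tr, xm, "value")
  }
  if (model$loss == "logistic") stats::plogis(f) else stats::plogis(2 * f)
}

#' Fit a pruned gradient boosting machine
#'
#' Huber-loss gradient boosting with validation-based early stopping:
#' [fit_gradient_boost()] with \code{loss = "huber"} plus a finite
#' \code{patience}.
#'
#' @param train,val complete [cohort()]s; \code{val} drives early stopping.
#' @param delta Huber outlier threshold (default 1).
#' @param patience early-stop rounds (default 10).
#' @param learning_rate step size (default 0.1).
#' @param max_rounds maximum rounds (default 200).
#' @param max_depth base-tree depth (default 3).
#' @return A \code{"gboost"} model (Huber configuration).
#' @export
fit_pgbm <- function(train, val, delta = 1, patience = 10L,
                     learning_rate = 0.1, max_rounds = 200L, max_depth = 3L) {
  stopifnot(delta > 0, patience >= 1L)
  fit_gradient_boost(train, val, loss = "huber",
                     learning_rate = learning_rate, max_rounds = max_rounds,
                     patience = patience, max_depth = max_depth, delta = delta)
}
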