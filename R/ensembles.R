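# The five combiners: AdaBoost, bagging, stacking, majority voting and
# Bayesian model averaging, each usable over any set of fitted learners
# exposing predict_prob().

# Matrix of base-learner positive-class probabilities, rows = observations.
prob_matrix <- function(models, x) {
  n <- nrow(feature_matrix(x))
  p <- vapply(models, predict_prob, numeric(n), x = x)
  matrix(p, nrow = n)
}

#' One AdaBoost round
#'
#' Fits a weak learner (a depth-limited stump by default) to the weighted
#' training data, computes its weighted error
#' \eqn{\epsilon_m = \sum_i w_i \mathbb{I}(h_m(x_i) \ne y_i)}, the learner
#' weight \eqn{\alpha_m = \tfrac12 \ln((1-\epsilon_m)/\epsilon_m)}, and the
#' renormalised sample-weight update
#' \eqn{w_i \propto w_i e^{-\alpha_m y_i h_m(x_i)}} (labels \eqn{\pm 1}).
#' A zero error is floored at \code{1e-10} before taking the log; an error
#' of at least 0.5 marks the round as rejected.
#'
#' @param train a complete [cohort()].
#' @param w positive sample weights summing to 1.
#' @param max_depth weak-learner depth (default 1, a stump).
#' @param mtry optional feature subsample for re-drawn rounds.
#' @return List: \code{h} (the stump), \code{eps}, \code{alpha},
#'   \code{w_next}, \code{rejected}.
#' @export
adaboost_round <- function(train, w, max_depth = 1L, mtry = Inf) {
  stopifnot(all(w > 0), abs(sum(w) - 1) < 1e-8)
  h <- grow_tree(train$x, train$y, w = w, type = "class",
                 max_depth = max_depth, min_leaf = 1L, mtry = mtry)
  pred <- as.integer(predict_tree_hard(h, train$x, "prob") >= 0.5)
  eps <- sum(w * (pred != train$y))
  if (eps >= 0.5) {
    return(list(h = h, eps = eps, alpha = 0, w_next = w, rejected = TRUE))
  }
  eps_eff <- max(eps, 1e-10)
  alpha <- 0.5 * log((1 - eps_eff) / eps_eff)
  yy <- 2 * train$y - 1
  hh <- 2 * pred - 1
  w_next <- w * exp(-alpha * yy * hh)
  w_next <- w_next / sum(w_next)
  list(h = h, eps = eps, alpha = alpha, w_next = w_next, rejected = FALSE)
}

#' Fit an AdaBoost ensemble of stumps
#'
#' Sequential reweighted boosting minimising the exponential loss
#' \eqn{\sum_i e^{-y_i F(x_i)}} with \eqn{F(x) = \sum_m \alpha_m h_m(x)}.
#' A round with weighted error \eqn{\ge 0.5} is re-drawn once with random
#' feature subsampling; a second failure stops boosting.
#'
#' @param train a complete [cohort()].
#' @param rounds maximum boosting rounds (default 50).
#' @param max_depth weak-learner depth (default 1).
#' @param seed integer seed (re-draws only).
#' @return An \code{"adaboost"} model with \code{alphas}, \code{epsilons},
#'   and the stump list.
#' @export
fit_adaboost <- function(train, rounds = 50L, max_depth = 1L, seed = 2025L) {
  n <- length(train$y)
  w <- rep(1 / n, n)
  hs <- list(); alphas <- numeric(0); epss <- numeric(0)
  with_seed(seed, {
    for (m in seq_len(rounds)) {
      r <- adaboost_round(train, w, max_depth = max_depth)
      if (r$rejected) {
        mtry <- max(1L, floor(sqrt(ncol(train$x))))
        r <- adaboost_round(train, w, max_depth = max_depth, mtry = mtry)
        if (r$rejected) break
      }
      hs[[length(hs) + 1L]] <- r$h
      alphas <- c(alphas, r$alpha)
      epss <- c(epss, r$eps)
      w <- r$w_next
      if (r$eps < 1e-10) break  # perfect stump; F already separates
    }
  })
  structure(list(stumps = hs, alphas = alphas, epsilons = epss,
                 features = colnames(train$x)),
            class = "adaboost")
}

adaboost_score <- function(model, x) {
  xm <- feature_matrix(x)
  f <- numeric(nrow(xm))
  for (m in seq_along(model$stumps)) {
    hm <- 2 * (predict_tree_hard(model$stumps[[m]], xm, "prob") >= 0.5) - 1
    f <- f + model$alphas[m] * hm
  }
  f
}

#' @export
predict_prob.adaboost <- function(model, x) {
  stats::plogis(2 * adaboost_score(model, x))
}

#' Fit a bagging ensemble
#'
#' Trains \code{B} copies of a base learner on bootstrap resamples (drawn
#' with replacement) and classifies by majority vote; the reported
#' probability is the vote share for the positive class.
#'
#' @param train a complete [cohort()].
#' @param base_fit function \code{cohort -> model}; default a hard CART.
#' @param B number of bags (>= 1, default 25).
#' @param seed integer seed.
#' @return A \code{"bagging"} model.
#' @export
fit_bagging <- function(train, base_fit = fit_cart, B = 25L, seed = 2025L) {
  stopifnot(B >= 1L)
  with_seed(seed, {
    bags <- lapply(seq_len(B), function(b) {
      rows <- sample.int(nrow(train$x), replace = TRUE)
      list(model = base_fit(cohort_rows(train, rows)), rows = rows)
    })
    structure(list(models = lapply(bags, `[[`, "model"),
                   bootstrap_rows = lapply(bags, `[[`, "rows"),
                   features = colnames(train$x)),
              class = "bagging")
  })
}

#' @export
predict_prob.bagging <- function(model, x) {
  votes <- vapply(model$models,
                  function(m) as.numeric(predict_prob(m, x) >= 0.5),
                  numeric(nrow(feature_matrix(x))))
  if (nrow(feature_matrix(x)) == 1L) votes <- matrix(votes, nrow = 1L)
  rowMeans(votes)
}

#' Majority vote over per-learner class labels
#'
#' Returns the modal class. A vote tie is broken by the mean positive-class
#' probability against 0.5; a residual exact tie goes to the positive class.
#'
#' @param labels integer vector (or matrix, rows = observations) of 0/1
#'   votes, one per learner.
#' @param probs matching positive-class probabilities.
#' @return Integer class (vector for matrix input).
#' @examples
#' majority_vote(c(1, 1, 0), c(0.9, 0.7, 0.2))  # 1
#' @export
majority_vote <- function(labels, probs = NULL) {
  if (is.matrix(labels)) {
    return(vapply(seq_len(nrow(labels)), function(i)
      majority_vote(labels[i, ], if (!is.null(probs)) probs[i, ]),
      integer(1)))
  }
  stopifnot(length(labels) >= 1L)
  ones <- sum(labels == 1L); zeros <- length(labels) - ones
  if (ones != zeros) return(as.integer(ones > zeros))
  if (!is.null(probs)) {
    mp <- mean(probs)
    if (mp != 0.5) return(as.integer(mp > 0.5))
  }
  1L
}

#' Average positive-class probabilities
#'
#' The soft-voting combiner \eqn{\hat y = \tfrac1M \sum_m h_m(x)}.
#'
#' @param probs numeric vector (or matrix, rows = observations) of
#'   probabilities in \eqn{[0, 1]}.
#' @return The arithmetic mean (rowwise for a matrix).
#' @export
average_probs <- function(probs) {
  stopifnot(all(probs >= 0 & probs <= 1))
  if (is.matrix(probs)) rowMeans(probs) else mean(probs)
}

#' Fit a voting ensemble over fitted learners
#'
#' @param models list of fitted learners (each supporting [predict_prob()]).
#' @return A \code{"voting"} model; its predicted probability is the mean
#'   base probability, and its hard class is the majority vote with the
#'   probability tie-break.
#' @export
fit_voting <- function(models) {
  stopifnot(length(models) >= 1L)
  structure(list(models = models), class = "voting")
}

#' @export
predict_prob.voting <- function(model, x) {
  rowMeans(prob_matrix(model$models, x))
}

#' Hard-vote classes of a voting ensemble
#'
#' @param model a \code{"voting"} model.
#' @param x features.
#' @return Integer 0/1 classes by majority vote.
#' @export
predict_vote <- function(model, x) {
  p <- prob_matrix(model$models, x)
  majority_vote((p >= 0.5) + 0L, p)
}

#' Fit a stacking ensemble
#'
#' Builds the meta-feature matrix \eqn{Z} from the base learners'
#' positive-class probabilities on the hold-out validation rows and fits a
#' logistic-regression meta-learner \eqn{H} on it (IRLS via \code{glm};
#' complete separation falls back to a ridge-stabilised IRLS with a note).
#' Prediction applies \eqn{H} to the base probabilities of new rows, so
#' test rows never enter meta-feature construction.
#'
#' @param models list of fitted base learners (usually >= 2; a single
#'   learner degenerates to probability calibration).
#' @param val hold-out [cohort()] for the meta-features.
#' @return A \code{"stacking"} model with \code{Z}, meta coefficients and
#'   a \code{ridged} flag.
#' @export
fit_stacking <- function(models, val) {
  stopifnot(length(models) >= 1L)
  Z <- prob_matrix(models, val)
  colnames(Z) <- paste0("base", seq_along(models))
  df <- data.frame(y = val$y, Z)
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  coefs <- stats::coef(fit)
  ridged <- FALSE
  if (anyNA(coefs) || any(abs(coefs[-1]) > 30)) {
    coefs <- ridge_irls(cbind(1, Z), val$y, lambda = 1e-2)
    ridged <- TRUE
  }
  structure(list(models = models, Z = Z, coef = unname(coefs),
                 ridged = ridged),
            class = "stacking")
}

# Ridge-stabilised IRLS for a logistic fit under (near-)separation.
ridge_irls <- function(X, y, lambda = 1e-2, max_iter = 100L, tol = 1e-10) {
  beta <- numeric(ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    Wd <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / Wd
    beta <- solve(crossprod(X, Wd * X) + pen, crossprod(X, Wd * z))
    ll <- sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  drop(beta)
}

#' @export
predict_prob.stacking <- function(model, x) {
  Z <- prob_matrix(model$models, x)
  stats::plogis(drop(cbind(1, Z) %*% model$coef))
}

#' Fit a Bayesian-model-averaging ensemble
#'
#' Approximates each candidate's model evidence by the exponentiated
#' validation log-likelihood with uniform model priors, normalises the
#' posterior weights through log-sum-exp so \eqn{\sum_i p_i = 1}, and
#' predicts the posterior-weighted mean \eqn{\hat y = \sum_i p_i f_i(x)}.
#' Candidate probabilities are floored at \code{1e-12} so an overconfident
#' model cannot produce an infinite deviance.
#'
#' @param models list of fitted candidate learners.
#' @param val nonempty hold-out [cohort()].
#' @return A \code{"bma"} model with posterior \code{weights} and the
#'   per-candidate validation log-likelihoods.
#' @export
fit_bma <- function(models, val) {
  stopifnot(length(models) >= 1L, nrow(val$x) >= 1L)
  ll <- vapply(models, function(m) {
    p <- pmin(pmax(predict_prob(m, val), 1e-12), 1 - 1e-12)
    sum(val$y * log(p) + (1 - val$y) * log(1 - p))
  }, numeric(1))
  lw <- ll - max(ll)
  w <- exp(lw) / sum(exp(lw))
  structure(list(models = models, weights = w, loglik = ll),
            class = "bma")
}

#' @export
predict_prob.bma <- function(model, x) {
  drop(prob_matrix(model$models, x) %*% model$weights)
}
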