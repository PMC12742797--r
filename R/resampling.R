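#' SMOTE interpolation step
#'
#' The elementwise synthetic-sample rule
#' \eqn{x_{new} = x_i + \lambda (x_{nn} - x_i)} for a minority point
#' \eqn{x_i}, one of its minority-class nearest neighbours \eqn{x_{nn}}, and
#' \eqn{\lambda \in [0, 1]}.
#'
#' @param x_i,x_nn numeric vectors of equal length.
#' @param lambda interpolation weight in \eqn{[0, 1]}.
#' @return The interpolated vector.
#' @examples
#' smote_interpolate(c(0, 0), c(2, 4), 0.5)  # c(1, 2)
#' @export
smote_interpolate <- function(x_i, x_nn, lambda) {
  stopifnot(length(x_i) == length(x_nn))
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  x_i + lambda * (x_nn - x_i)
}

#' Balance a cohort by SMOTE oversampling
#'
#' Creates synthetic minority-class rows by interpolating between each
#' sampled minority point and one of its \code{k} minority-class nearest
#' neighbours (Euclidean distance on z-scored features), until
#' minority:majority equals \code{target_ratio}. Majority rows are never
#' touched. Binary features are thresholded at 0.5 after interpolation so
#' they stay 0/1. Intended for training data only — balancing before a
#' train/test split leaks synthetic copies of test-adjacent points.
#'
#' @param cohort a complete [cohort()].
#' @param k minority neighbours to interpolate toward (default 5).
#' @param target_ratio desired minority/majority count ratio in (0, 1],
#'   default 1 (a perfectly balanced 50/50 output).
#' @param seed integer seed.
#' @return The augmented [cohort()]; attribute \code{"n_synthetic"} gives
#'   the number of rows added and \code{"parents"} a two-column matrix of
#'   the originating minority row indices.
#' @export
smote_balance <- function(cohort, k = 5L, target_ratio = 1, seed = 1L) {
  stopifnot(k >= 1L, target_ratio > 0, target_ratio <= 1)
  y <- cohort$y
  minority <- if (sum(y == 1L) <= sum(y == 0L)) 1L else 0L
  idx_min <- which(y == minority)
  n_min <- length(idx_min); n_maj <- length(y) - n_min
  if (n_min <= k) {
    stop("minority count (", n_min, ") must exceed k = ", k,
         "; use a smaller k")
  }
  n_new <- round(target_ratio * n_maj) - n_min
  if (n_new <= 0) {
    attr(cohort, "n_synthetic") <- 0L
    return(cohort)
  }
  xm <- cohort$x[idx_min, , drop = FALSE]
  z <- scale(xm)
  z[, attr(z, "scaled:scale") == 0 | is.na(attr(z, "scaled:scale"))] <- 0
  d2 <- as.matrix(stats::dist(z))^2
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  is_bin <- cohort$kinds == "binary"
  with_seed(seed, {
    base <- sample(rep_len(seq_len(n_min), n_new))
    pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
    lam <- stats::runif(n_new)
    newx <- xm[base, , drop = FALSE] +
      lam * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    if (any(is_bin)) {
      newx[, is_bin] <- (newx[, is_bin, drop = FALSE] >= 0.5) + 0
    }
    out <- cohort
    out$x <- rbind(cohort$x, newx)
    out$y <- c(y, rep(minority, n_new))
    attr(out, "n_synthetic") <- as.integer(n_new)
    attr(out, "parents") <- cbind(idx_min[base], idx_min[pick])
    out
  })
}

#' Yamane sample size
#'
#' The closed-form rule \eqn{n = N / (1 + N e^2)} for a population of size
#' \eqn{N} at margin of error \eqn{e}, rounded to the nearest integer.
#' Note the canonical worked case: at \eqn{N = 459{,}574}, \eqn{e = 0.01}
#' the formula evaluates to 9,787 (459,574 / 46.9574 = 9787.0), although
#' the value is sometimes quoted as approximately 9,789; this function
#' returns the exact arithmetic.
#'
#' @param N population size (>= 1).
#' @param e margin of error in (0, 1).
#' @return Integer sample size.
#' @examples
#' yamane_sample_size(1000, 0.05)    # 286
#' yamane_sample_size(459574, 0.01)  # 9787
#' @export
yamane_sample_size <- function(N, e) {
  stopifnot(N >= 1, e > 0, e < 1)
  as.integer(round(N / (1 + N * e^2)))
}

largest_remainder <- function(shares, total) {
  raw <- shares * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified subsample of a cohort
#'
#' Draws \code{n} rows without replacement with per-outcome-class counts
#' proportional to the population class shares (largest-remainder rounding).
#'
#' @param cohort a [cohort()].
#' @param n target size (strata count <= n <= rows).
#' @param seed integer seed.
#' @return The subsampled [cohort()].
#' @export
stratified_subsample <- function(cohort, n, seed = 1L) {
  y <- cohort$y
  strata <- sort(unique(y))
  if (n < length(strata)) stop("n smaller than the number of outcome strata")
  if (n > length(y)) stop("n exceeds the cohort size")
  counts <- largest_remainder(as.vector(table(factor(y, strata))) / length(y), n)
  with_seed(seed, {
    keep <- unlist(lapply(seq_along(strata), function(s) {
      pool <- which(y == strata[s])
      pool[sample.int(length(pool), counts[s])]
    }))
    cohort_rows(cohort, sort(keep))
  })
}

#' Stratified train/validation/test split
#'
#' Splits a cohort into disjoint, exhaustive train/validation/test parts,
#' stratified on the outcome, with the conventional 70/15/15 default.
#'
#' @param cohort a [cohort()].
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed integer seed.
#' @return List with cohorts \code{train}, \code{val}, \code{test} and the
#'   row-index vectors \code{idx} used for each.
#' @export
split_cohort <- function(cohort, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            all(fractions > 0))
  y <- cohort$y
  idx <- vector("list", 3)
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      pool <- sample(which(y == cls))
      counts <- largest_remainder(fractions, length(pool))
      offs <- cumsum(c(0, counts))
      for (p in 1:3) {
        idx[[p]] <- c(idx[[p]], pool[seq_len(counts[p]) + offs[p]])
      }
    }
  })
  idx <- lapply(idx, sort)
  parts <- lapply(idx, function(i) cohort_rows(cohort, i))
  for (p in parts) {
    if (length(unique(p$y)) < 2L) {
      stop("a split part contains a single outcome class; increase n")
    }
  }
  list(train = parts[[1]], val = parts[[2]], test = parts[[3]], idx = idx)
}

#' Stratified k-fold assignment
#'
#' Assigns every row of a cohort to exactly one of \code{folds} held-out
#' parts, stratified on the outcome.
#'
#' @param cohort a [cohort()].
#' @param folds number of folds (default 5).
#' @param seed integer seed.
#' @return List of \code{folds} elements, each with cohorts \code{fit} and
#'   \code{held} plus the held row indices \code{held_idx}.
#' @export
kfold <- function(cohort, folds = 5L, seed = 1L) {
  stopifnot(folds >= 2L)
  y <- cohort$y
  if (folds > min(table(y))) stop("folds exceed the minority class count")
  assign <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      pool <- sample(which(y == cls))
      assign[pool] <- rep_len(seq_len(folds), length(pool))
    }
  })
  lapply(seq_len(folds), function(f) {
    held <- which(assign == f)
    list(fit = cohort_rows(cohort, -held),
         held = cohort_rows(cohort, held),
         held_idx = held)
  })
}
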