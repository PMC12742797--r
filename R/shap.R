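# Shapley-value feature attribution on the probability scale, plus the
# global surrogate tree. Absent features are marginalised by averaging the
# model over a background sample ("interventional" value function).

coalition_value <- function(predict_fn, x, background, mask) {
  # mask: logical, TRUE = feature present (takes x's value)
  z <- background
  if (any(mask)) {
    z[, mask] <- matrix(x[mask], nrow(background), sum(mask), byrow = TRUE)
  }
  mean(predict_fn(z))
}

#' Exact Shapley attributions for one observation
#'
#' Enumerates all \eqn{2^M} feature coalitions (hence \eqn{M \le 12}) and
#' computes the classical Shapley value of each feature, with absent
#' features replaced by background rows and averaged out. Satisfies local
#' accuracy exactly: \eqn{f(x) = \phi_0 + \sum_i \phi_i}, where
#' \eqn{\phi_0} is the mean background prediction.
#'
#' @param predict_fn function mapping a feature matrix to predictions
#'   (probabilities).
#' @param x a single observation (numeric vector, training feature order).
#' @param background matrix of background rows (e.g. 100 seeded training
#'   rows).
#' @return A \code{"shap_explanation"}: \code{phi0}, named \code{phi},
#'   \code{fx}, \code{method = "exact"}.
#' @export
shap_exact <- function(predict_fn, x, background) {
  M <- length(x)
  if (M > 12L) {
    stop("exact enumeration is limited to 12 features; use shap_sample()")
  }
  background <- as.matrix(background)
  nC <- 2^M
  vals <- numeric(nC)
  masks <- matrix(FALSE, nC, M)
  for (s in seq_len(nC) - 1L) {
    mask <- as.logical(bitwAnd(s, 2^(seq_len(M) - 1L)))
    masks[s + 1L, ] <- mask
    vals[s + 1L] <- coalition_value(predict_fn, x, background, mask)
  }
  sizes <- rowSums(masks)
  phi <- numeric(M)
  wts <- factorial(0:(M - 1)) * factorial(M - 1 - (0:(M - 1))) / factorial(M)
  for (i in seq_len(M)) {
    without <- which(!masks[, i])
    with_i <- without + 2^(i - 1L)
    phi[i] <- sum(wts[sizes[without] + 1L] * (vals[with_i] - vals[without]))
  }
  names(phi) <- names(x)
  structure(list(phi0 = vals[1L], phi = phi,
                 fx = vals[nC], method = "exact"),
            class = "shap_explanation")
}

#' Sampled Shapley attributions for one observation
#'
#' Permutation-sampling estimator: for each of \code{n_perm} random feature
#' orderings a background row is progressively overwritten with the
#' observation's values, and each feature is credited with the change in
#' prediction when it is switched in. Unbiased for the exact Shapley value;
#' Monte-Carlo error shrinks as \eqn{1/\sqrt{n_{perm}}}.
#'
#' @param predict_fn prediction function (matrix in, numeric out).
#' @param x a single observation.
#' @param background background matrix.
#' @param n_perm number of sampled permutations (default 200).
#' @param seed integer seed.
#' @return A \code{"shap_explanation"} with \code{method = "sampling"}.
#' @export
shap_sample <- function(predict_fn, x, background, n_perm = 200L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  background <- as.matrix(background)
  M <- length(x)
  B <- nrow(background)
  with_seed(seed, {
    phi <- numeric(M)
    for (r in seq_len(n_perm)) {
      perm <- sample.int(M)
      z <- background[sample.int(B, 1L), , drop = FALSE]
      # evaluate the chain z, z+first feature, ..., x in one predict call
      chain <- matrix(rep(z, M + 1L), M + 1L, M, byrow = TRUE,
                      dimnames = list(NULL, colnames(background)))
      for (pos in seq_len(M)) {
        chain[(pos + 1L):(M + 1L), perm[pos]] <- x[perm[pos]]
      }
      pv <- predict_fn(chain)
      phi[perm] <- phi[perm] + diff(pv)
    }
    phi <- phi / n_perm
    names(phi) <- names(x)
    phi0 <- mean(predict_fn(background))
    fx <- predict_fn(matrix(x, 1L, M,
                            dimnames = list(NULL, colnames(background))))
    structure(list(phi0 = phi0, phi = phi, fx = as.numeric(fx),
                   method = "sampling", n_perm = n_perm, seed = seed),
              class = "shap_explanation")
  })
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> method=%s phi0=%.4f f(x)=%.4f\n",
              x$method, x$phi0, x$fx))
  print(round(sort(x$phi, decreasing = TRUE), 4))
  invisible(x)
}

#' Global feature ranking by mean absolute attribution
#'
#' @param explanations list of \code{"shap_explanation"} objects over a row
#'   set.
#' @return Data frame of features sorted by mean \eqn{|\phi_i|}
#'   (descending; ties keep feature order).
#' @export
mean_abs_shap <- function(explanations) {
  stopifnot(length(explanations) >= 1L)
  mat <- vapply(explanations, function(e) abs(e$phi),
                numeric(length(explanations[[1]]$phi)))
  if (length(explanations[[1]]$phi) == 1L) mat <- matrix(mat, nrow = 1L)
  m <- rowMeans(mat)
  ord <- order(-m, seq_along(m))
  data.frame(feature = names(explanations[[1]]$phi)[ord],
             mean_abs_phi = unname(m[ord]))
}

#' Global surrogate decision tree
#'
#' Fits a depth-limited hard CART to the explained model's predicted labels
#' on half of the cohort and reports fidelity — the fraction of the other
#' half on which surrogate and model agree — as a transparency check.
#'
#' @param predict_fn prediction function of the model to explain.
#' @param cohort a complete [cohort()].
#' @param max_depth surrogate depth budget (default 4).
#' @param seed integer seed for the half split.
#' @return A \code{"surrogate_report"}: the surrogate tree, \code{fidelity}
#'   in \eqn{[0, 1]}, and \code{train_fidelity}.
#' @export
surrogate_tree <- function(predict_fn, cohort, max_depth = 4L, seed = 1L) {
  x <- cohort$x
  labels <- as.integer(predict_fn(x) >= 0.5)
  n <- nrow(x)
  with_seed(seed, {
    half <- sample.int(n, floor(n / 2))
    tree <- grow_tree(x[half, , drop = FALSE], labels[half], type = "class",
                      max_depth = max_depth, min_leaf = 1L)
    agree <- function(rows) {
      mean((predict_tree_hard(tree, x[rows, , drop = FALSE], "prob") >= 0.5) ==
             (labels[rows] == 1L))
    }
    structure(list(tree = tree,
                   fidelity = agree(setdiff(seq_len(n), half)),
                   train_fidelity = agree(half),
                   max_depth = max_depth),
              class = "surrogate_report")
  })
}

#' @export
print.surrogate_report <- function(x, ...) {
  cat(sprintf("<surrogate_report> depth<=%d fidelity=%.3f (train %.3f)\n",
              x$max_depth, x$fidelity, x$train_fidelity))
  print_tree_rules(x$tree, feature_names = NULL)
  invisible(x)
}

print_tree_rules <- function(node, feature_names = NULL, indent = "") {
  if (node$leaf) {
    cat(indent, sprintf("-> class %d (p1=%.3f, n=%d)\n",
                        as.integer(node$prob[2] >= 0.5), node$prob[2],
                        node$n), sep = "")
    return(invisible())
  }
  fname <- if (!is.null(feature_names)) feature_names[node$feature] else
    paste0("x", node$feature)
  cat(indent, sprintf("if %s <= %.4g:\n", fname, node$theta), sep = "")
  print_tree_rules(node$left, feature_names, paste0(indent, "  "))
  cat(indent, "else:\n", sep = "")
  print_tree_rules(node$right, feature_names, paste0(indent, "  "))
}
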