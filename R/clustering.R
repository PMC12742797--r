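# Domain-wise k-means risk-subgroup analysis: Lloyd iterations with
# k-means++ seeding and restarts, silhouette-based k selection, chi-square
# association with the outcome, and cluster-dummy logistic regression
# producing odds ratios with Wald intervals.

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[j, ] <- x[sample.int(n, 1), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- kmeanspp_init(x, k)
  assign_old <- integer(n)
  J_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
      2 * tcrossprod(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    # repair empty clusters by reseeding at the farthest point
    for (g in which(tabulate(assign, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), assign)])
      assign[far] <- g
    }
    J_trace <- c(J_trace, sum(rowSums((x - centers[assign, , drop = FALSE])^2)))
    for (g in seq_len(k)) {
      centers[g, ] <- colMeans(x[assign == g, , drop = FALSE])
    }
    if (identical(assign, assign_old)) break
    assign_old <- assign
  }
  J <- sum(rowSums((x - centers[assign, , drop = FALSE])^2))
  list(centers = centers, assignments = assign, J = J,
       iterations = it, J_trace = J_trace)
}

#' K-means clustering (Lloyd with k-means++ seeding and restarts)
#'
#' Minimises the within-cluster sum of squares
#' \eqn{J = \sum_{i=1}^{k} \sum_{x_j \in C_i} \lVert x_j - \mu_i \rVert^2}.
#' Runs \code{restarts} independent k-means++ initialisations and keeps the
#' solution with the smallest \eqn{J}; empty clusters are repaired by
#' reseeding at the farthest point.
#'
#' @param x numeric matrix (standardise/encode features first).
#' @param k number of clusters (<= number of distinct rows).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @param restarts independent restarts (default 10).
#' @return A \code{"kmeans_model"}: \code{centers}, 1-based
#'   \code{assignments}, objective \code{J}, per-iteration \code{J_trace}
#'   of the winning restart.
#' @export
kmeans_fit <- function(x, k, seed = 1L, max_iter = 100L, restarts = 10L) {
  x <- as.matrix(x)
  if (k > nrow(unique(x))) stop("k exceeds the number of distinct rows")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      run <- lloyd_once(x, k, max_iter)
      if (is.null(best) || run$J < best$J) best <- run
    }
    structure(c(best, list(k = k, seed = seed)), class = "kmeans_model")
  })
}

#' Mean silhouette score
#'
#' For each point, \eqn{s = (b - a)/\max(a, b)} with \eqn{a} the mean
#' distance to its own cluster and \eqn{b} the smallest mean distance to
#' another cluster; singletons contribute 0. Requires at least 2 clusters.
#'
#' @param x numeric matrix.
#' @param assignments integer cluster labels (1-based).
#' @return Mean silhouette in \eqn{[-1, 1]}.
#' @export
silhouette_score <- function(x, assignments) {
  ks <- sort(unique(assignments))
  if (length(ks) < 2L) stop("silhouette requires at least 2 clusters")
  D <- as.matrix(stats::dist(as.matrix(x)))
  n <- nrow(D)
  s <- numeric(n)
  sizes <- table(factor(assignments, ks))
  for (i in seq_len(n)) {
    own <- assignments[i]
    if (sizes[as.character(own)] == 1L) { s[i] <- 0; next }
    a <- sum(D[i, assignments == own]) / (sizes[as.character(own)] - 1L)
    b <- min(vapply(ks[ks != own], function(g)
      mean(D[i, assignments == g]), numeric(1)))
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

#' Choose the cluster count by silhouette
#'
#' Fits [kmeans_fit()] for each candidate \code{k} and returns the one with
#' the highest mean silhouette; ties go to the smaller \code{k}.
#'
#' @param x numeric matrix.
#' @param k_range candidate counts (default 2:10).
#' @param seed integer seed.
#' @param restarts restarts per candidate.
#' @return List: chosen \code{k}, its \code{silhouette}, the fitted
#'   \code{model}, and the silhouette profile.
#' @export
select_k <- function(x, k_range = 2:10, seed = 1L, restarts = 10L) {
  stopifnot(length(k_range) >= 1L)
  x <- as.matrix(x)
  k_range <- k_range[k_range <= nrow(unique(x))]
  fits <- lapply(seq_along(k_range), function(i)
    kmeans_fit(x, k_range[i], seed = seed + i, restarts = restarts))
  sil <- vapply(fits, function(f) silhouette_score(x, f$assignments),
                numeric(1))
  pick <- which(sil >= max(sil) - 1e-12)[1]  # ties to the smaller k
  list(k = k_range[pick], silhouette = sil[pick], model = fits[[pick]],
       profile = data.frame(k = k_range, silhouette = sil))
}

#' Chi-square association between clusters and outcome
#'
#' Pearson chi-square on the k-by-2 contingency table of cluster label
#' against outcome (no continuity correction), df = k - 1.
#'
#' @param assignments integer cluster labels.
#' @param outcome 0/1 vector.
#' @return List: \code{statistic}, \code{df}, \code{p_value}.
#' @export
chisq_association <- function(assignments, outcome) {
  tab <- table(assignments, outcome)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has an empty row or column")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Odds ratios and Wald intervals from logistic coefficients
#'
#' The transform layer of the cluster tables: \eqn{OR = e^{\beta}} and the
#' 95 percent Wald interval \eqn{e^{\beta \pm 1.96\,SE}}.
#'
#' @param coef,se numeric vectors of coefficients and standard errors.
#' @return Data frame: \code{or}, \code{ci_lower}, \code{ci_upper}.
#' @examples
#' or_from_coef(1.332, 0.088)  # OR 3.79, CI [3.19, 4.50]
#' @export
or_from_coef <- function(coef, se) {
  data.frame(or = exp(coef),
             ci_lower = exp(coef - 1.96 * se),
             ci_upper = exp(coef + 1.96 * se))
}

#' Cluster-dummy logistic regression table
#'
#' IRLS logistic fit of the outcome on k-1 cluster indicator dummies with
#' cluster 0 (the lowest label) as reference, reporting the familiar
#' Coef / Std Err / p / OR / CI layout. Complete separation triggers a
#' ridge-stabilised refit, flagged in the result.
#'
#' @param assignments integer cluster labels.
#' @param outcome 0/1 vector.
#' @return Data frame with rows Intercept, Cluster 1, ...; attribute
#'   \code{"ridged"} marks a stabilised fit.
#' @export
cluster_logit <- function(assignments, outcome) {
  f <- factor(assignments)
  if (!sum(f == levels(f)[1])) stop("reference cluster is empty")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ f, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities", conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  if (sep || any(abs(cf[, 1]) > 15)) {
    sep <- TRUE
    X <- stats::model.matrix(~f)
    beta <- ridge_irls(X, outcome, lambda = 1e-3)
    p <- stats::plogis(drop(X %*% beta))
    W <- pmax(p * (1 - p), 1e-10)
    V <- solve(crossprod(X, W * X) + diag(1e-3, ncol(X)))
    se <- sqrt(diag(V))
    cf <- cbind(beta, se, beta / se,
                2 * stats::pnorm(-abs(beta / se)))
  }
  out <- data.frame(
    term = c("Intercept", paste("Cluster",
                                seq_len(nrow(cf) - 1L))),
    coef = unname(cf[, 1]), std_err = unname(cf[, 2]),
    p_value = unname(cf[, 4]))
  out <- cbind(out, or_from_coef(out$coef, out$std_err))
  attr(out, "ridged") <- sep
  out
}

encode_for_clustering <- function(cohort, features) {
  x <- cohort$x[, features, drop = FALSE]
  kinds <- cohort$kinds[features]
  for (j in seq_along(features)) {
    if (kinds[j] != "binary") {
      s <- stats::sd(x[, j])
      x[, j] <- if (s > 0) (x[, j] - mean(x[, j])) / s else 0
    }
  }
  x
}

#' Domain-wise risk-subgroup report
#'
#' Runs the full clustering analysis: for each risk-factor domain (and for
#' the full feature set) z-score-encodes the features, selects k by
#' silhouette, tests the cluster/outcome association by chi-square, and
#' fits the cluster-dummy logistic regression.
#'
#' @param cohort a complete [cohort()].
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed integer seed.
#' @param restarts k-means restarts per candidate.
#' @param domains domains to analyse; default the four domains plus
#'   \code{"full"}.
#' @return A named list of per-domain reports (class
#'   \code{"cluster_report"}), each with \code{k}, \code{silhouette},
#'   \code{chisq}, \code{logit} and the \code{assignments}.
#' @export
risk_cluster_report <- function(cohort, k_range = 2:10, seed = 1L,
                                restarts = 10L,
                                domains = c(FEATURE_DOMAINS, "full")) {
  out <- lapply(domains, function(dm) {
    feats <- if (dm == "full") colnames(cohort$x) else
      names(cohort$domains)[cohort$domains == dm]
    if (length(feats) < 1L) return(NULL)
    x <- encode_for_clustering(cohort, feats)
    sel <- select_k(x, k_range = k_range, seed = seed, restarts = restarts)
    assign0 <- sel$model$assignments - 1L  # cluster 0 = reference
    structure(list(domain = dm, k = sel$k, silhouette = sel$silhouette,
                   chisq = chisq_association(assign0, cohort$y),
                   logit = cluster_logit(assign0, cohort$y),
                   assignments = assign0, profile = sel$profile),
              class = "cluster_report")
  })
  stats::setNames(out, domains)
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> domain=%s k=%d silhouette=%.3f chi2=%.1f (df=%d, p=%.3g)\n",
              x$domain, x$k, x$silhouette, x$chisq$statistic, x$chisq$df,
              x$chisq$p_value))
  print(x$logit, digits = 3)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster assignments; 1 means
#' identical partitions, 0 is the expected agreement of random labels.
#'
#' @param a,b integer label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expect <- si * sj / n
  (sij - expect) / ((si + sj) / 2 - expect)
}
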