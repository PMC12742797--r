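#' K-nearest-neighbour imputation
#'
#' Fills each missing cell from the \code{k} complete rows nearest in
#' Euclidean distance computed on the features observed in both rows.
#' Continuous features are imputed by the neighbour mean; binary and ordinal
#' features by the neighbour mode, ties broken toward the smaller category
#' value. Observed cells are never changed.
#'
#' @param cohort a [cohort()], possibly with \code{NA} feature cells.
#' @param k number of neighbours (default 5).
#' @return A complete [cohort()] with attribute \code{"imputed_cells"}.
#' @export
impute_knn <- function(cohort, k = 5L) {
  stopifnot(k >= 1L)
  x <- cohort$x
  if (!anyNA(x)) {
    attr(x, "imputed_cells") <- 0L
    cohort$x <- x
    return(cohort)
  }
  all_missing <- colSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    stop("column(s) entirely missing: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  }
  if (any(rowSums(!is.na(x)) == 0L)) {
    stop("every row must have at least one observed feature")
  }
  complete <- which(stats::complete.cases(x))
  if (length(complete) < 1L) stop("no complete rows available as donors")
  kk <- min(k, length(complete))
  xc <- x[complete, , drop = FALSE]
  need <- which(!stats::complete.cases(x))
  n_imp <- 0L
  for (i in need) {
    obs <- which(!is.na(x[i, ]))
    # mean squared difference over co-observed features, scale-free enough
    # for survey features already on comparable ranges
    d2 <- colMeans((t(xc[, obs, drop = FALSE]) - x[i, obs])^2)
    nb <- complete[order(d2)[seq_len(kk)]]
    for (j in which(is.na(x[i, ]))) {
      vals <- x[nb, j]
      if (cohort$kinds[j] == "continuous") {
        x[i, j] <- mean(vals)
      } else {
        tab <- table(vals)
        best <- as.numeric(names(tab)[tab == max(tab)])
        x[i, j] <- min(best)
      }
      n_imp <- n_imp + 1L
    }
  }
  attr(x, "imputed_cells") <- n_imp
  cohort$x <- x
  cohort
}

#' Flag outliers by the interquartile-range rule
#'
#' Returns the indices of values outside
#' \eqn{[Q_1 - m\,\mathrm{IQR},\; Q_3 + m\,\mathrm{IQR}]} where the quartiles
#' use linear-interpolation (type-7) quantiles. A constant column has zero
#' IQR and yields no flags.
#'
#' @param values numeric vector (one feature column).
#' @param multiplier the IQR multiplier \eqn{m} (default 1.5).
#' @return Integer vector of flagged indices (possibly empty).
#' @examples
#' flag_outliers_iqr(c(1, 2, 3, 4, 100))  # flags index 5
#' @export
flag_outliers_iqr <- function(values, multiplier = 1.5) {
  stopifnot(sum(is.finite(values)) >= 4L)
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - multiplier * iqr
  hi <- q[2] + multiplier * iqr
  which(values < lo | values > hi)
}

#' Flag multivariate outliers by Mahalanobis distance
#'
#' Computes squared Mahalanobis distances of the continuous features from
#' their mean and flags rows exceeding the upper-\code{alpha} quantile of the
#' chi-square distribution with \code{d} degrees of freedom (\code{d} =
#' number of continuous features). A singular covariance is
#' ridge-regularised by adding \code{1e-6 * trace(S)/d} to the diagonal.
#'
#' @param cohort a complete [cohort()].
#' @param alpha upper tail probability (default 0.01).
#' @param ridge logical; regularise a singular covariance instead of failing.
#' @return Integer vector of flagged row indices.
#' @export
flag_outliers_mahalanobis <- function(cohort, alpha = 0.01, ridge = TRUE) {
  cont <- which(cohort$kinds == "continuous")
  if (!length(cont)) cont <- seq_along(cohort$kinds)
  xm <- cohort$x[, cont, drop = FALSE]
  if (anyNA(xm)) stop("impute missing values before outlier flagging")
  d <- ncol(xm)
  S <- stats::cov(xm)
  if (rcond_sym(S) < 1e-12 || nrow(xm) <= d) {
    if (!ridge) stop("singular covariance; enable ridge regularisation")
    S <- S + diag(1e-6 * sum(diag(S)) / d, d)
  }
  md2 <- stats::mahalanobis(xm, colMeans(xm), S)
  cut <- stats::qchisq(1 - alpha, df = d)
  which(md2 > cut)
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Drop near-constant features
#'
#' Removes features whose sample variance is less than or equal to
#' \code{threshold}. The outcome is never a feature and is never removed.
#'
#' @param cohort a complete [cohort()].
#' @param threshold nonnegative variance cutoff (default 0).
#' @return The filtered [cohort()] with attribute \code{"dropped"} listing
#'   removed feature names.
#' @export
variance_filter <- function(cohort, threshold = 0) {
  stopifnot(threshold >= 0)
  v <- apply(cohort$x, 2, stats::var)
  drop <- names(v)[v <= threshold]
  if (length(drop) == ncol(cohort$x)) {
    stop("variance filter would drop every feature")
  }
  out <- if (length(drop)) cohort_features(cohort, setdiff(colnames(cohort$x), drop)) else cohort
  attr(out, "dropped") <- drop
  out
}

#' Standardise cohort features
#'
#' \code{zscore} centres and scales each non-binary feature to mean 0 and
#' standard deviation 1; \code{minmax} maps each non-binary feature onto
#' \eqn{[0, 1]}. Binary features are left untouched so their 0/1 coding
#' survives.
#'
#' @param cohort a complete [cohort()].
#' @param mode \code{"zscore"} or \code{"minmax"}.
#' @return The standardised [cohort()] with attribute \code{"scaling"}, a
#'   data frame of per-feature \code{(center, scale)}.
#' @export
standardize <- function(cohort, mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  x <- cohort$x
  scalable <- which(cohort$kinds != "binary")
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  for (j in scalable) {
    v <- x[, j]
    if (mode == "zscore") {
      s <- stats::sd(v)
      if (s == 0) stop("constant continuous feature under zscore: ", colnames(x)[j])
      center[j] <- mean(v); scale[j] <- s
    } else {
      r <- range(v)
      center[j] <- r[1]
      scale[j] <- if (diff(r) > 0) diff(r) else 1
    }
    x[, j] <- (v - center[j]) / scale[j]
  }
  cohort$x <- x
  attr(cohort, "scaling") <- data.frame(feature = colnames(x),
                                        center = center, scale = scale)
  cohort
}

#' Run the full preprocessing pipeline
#'
#' KNN imputation, IQR and Mahalanobis outlier flagging, variance filtering
#' and standardisation, in that order, returning the processed cohort and an
#' audit report. Outliers are flagged, not removed, unless
#' \code{drop_outliers = TRUE}: the removal rule is a user choice.
#'
#' @param cohort a [cohort()], possibly with missing cells.
#' @param k neighbours for imputation.
#' @param iqr_multiplier IQR rule multiplier.
#' @param mahalanobis_alpha chi-square tail for multivariate flags.
#' @param var_threshold variance cutoff.
#' @param scale_mode \code{"zscore"} or \code{"minmax"}.
#' @param drop_outliers drop flagged rows before scaling (default FALSE).
#' @return List with elements \code{cohort} (processed) and \code{report}
#'   (class \code{"preprocess_report"}: imputed cell count, flagged rows,
#'   dropped features, scaling table).
#' @export
preprocess <- function(cohort, k = 5L, iqr_multiplier = 1.5,
                       mahalanobis_alpha = 0.01, var_threshold = 0,
                       scale_mode = "zscore", drop_outliers = FALSE) {
  co <- impute_knn(cohort, k = k)
  imputed <- attr(co$x, "imputed_cells")
  cont <- which(co$kinds == "continuous")
  iqr_rows <- sort(unique(unlist(
    lapply(cont, function(j) flag_outliers_iqr(co$x[, j], iqr_multiplier)))))
  mah_rows <- flag_outliers_mahalanobis(co, alpha = mahalanobis_alpha)
  if (drop_outliers) {
    bad <- union(iqr_rows, mah_rows)
    if (length(bad)) co <- cohort_rows(co, -bad)
  }
  co <- variance_filter(co, var_threshold)
  dropped <- attr(co, "dropped")
  co <- standardize(co, scale_mode)
  report <- structure(
    list(imputed_cells = imputed,
         iqr_outlier_rows = as.integer(iqr_rows),
         mahalanobis_outlier_rows = as.integer(mah_rows),
         dropped_low_variance = dropped,
         scaling = attr(co, "scaling"),
         outliers_dropped = drop_outliers),
    class = "preprocess_report")
  list(cohort = co, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n",
      sprintf("  imputed cells: %d\n", x$imputed_cells),
      sprintf("  IQR-flagged rows: %d\n", length(x$iqr_outlier_rows)),
      sprintf("  Mahalanobis-flagged rows: %d\n",
              length(x$mahalanobis_outlier_rows)),
      sprintf("  low-variance features dropped: %s\n",
              if (length(x$dropped_low_variance))
                paste(x$dropped_low_variance, collapse = ", ") else "none"),
      sep = "")
  invisible(x)
}
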