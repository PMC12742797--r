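#' Construct a cohort object
#'
#' A cohort bundles a numeric feature matrix, a binary outcome vector, and
#' per-feature metadata: the measurement kind (\code{"binary"},
#' \code{"ordinal"} or \code{"continuous"}) and the risk-factor domain
#' (\code{"demographic"}, \code{"clinical"}, \code{"behavioral"} or
#' \code{"healthcare"}). Every modelling, resampling and clustering function
#' in the package consumes this object.
#'
#' Missing feature values are represented as \code{NA} and must be resolved
#' by [impute_knn()] before model fitting; the outcome may not be missing.
#'
#' @param x numeric matrix (rows = subjects, columns = features) with unique
#'   column names. \code{NA} entries mark missing values.
#' @param y outcome vector coercible to \{0, 1\}; length \code{nrow(x)}.
#' @param kinds character vector of feature kinds, one per column of
#'   \code{x}, values in \code{c("binary", "ordinal", "continuous")}.
#' @param domains character vector of feature domains, one per column,
#'   values in \code{c("demographic", "clinical", "behavioral", "healthcare")}.
#' @return An object of class \code{"cohort"}: a list with elements
#'   \code{x}, \code{y}, \code{kinds}, \code{domains}.
#' @examples
#' x <- cbind(age = c(40, 55, 63), bmi = c(22.1, 31.0, 27.4))
#' cohort(x, c(0, 1, 0),
#'        kinds = c("ordinal", "continuous"),
#'        domains = c("demographic", "clinical"))
#' @export
cohort <- function(x, y, kinds, domains) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  y <- as.integer(y)
  obj <- structure(
    list(x = x, y = y,
         kinds = stats::setNames(as.character(kinds), colnames(x)),
         domains = stats::setNames(as.character(domains), colnames(x))),
    class = "cohort")
  validate_cohort(obj)
  obj
}

FEATURE_KINDS <- c("binary", "ordinal", "continuous")
FEATURE_DOMAINS <- c("demographic", "clinical", "behavioral", "healthcare")

validate_cohort <- function(obj, allow_missing = TRUE) {
  x <- obj$x
  if (ncol(x) < 1L) stop("cohort must have at least one feature")
  if (nrow(x) < 2L) stop("cohort must have at least two rows")
  if (anyDuplicated(colnames(x))) stop("feature names must be unique")
  if (!allow_missing && anyNA(x)) stop("cohort contains missing values")
  if (length(obj$y) != nrow(x)) stop("outcome length must match rows")
  if (anyNA(obj$y) || !all(obj$y %in% c(0L, 1L))) {
    stop("outcome must be strictly binary (0/1)")
  }
  if (length(obj$kinds) != ncol(x) || !all(obj$kinds %in% FEATURE_KINDS)) {
    stop("feature kinds must be one of ", paste(FEATURE_KINDS, collapse = ", "),
         " with one entry per feature")
  }
  if (length(obj$domains) != ncol(x) || !all(obj$domains %in% FEATURE_DOMAINS)) {
    stop("feature domains must be one of ",
         paste(FEATURE_DOMAINS, collapse = ", "), " with one entry per feature")
  }
  invisible(obj)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x %d features; outcome prevalence %.2f%%\n",
              nrow(x$x), ncol(x$x), 100 * mean(x$y)))
  tab <- table(factor(x$domains, levels = FEATURE_DOMAINS))
  cat("  domains:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (anyNA(x$x)) {
    cat(sprintf("  missing cells: %d\n", sum(is.na(x$x))))
  }
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$x)

#' Subset a cohort by row index
#'
#' @param x a [cohort()].
#' @param rows integer or logical row index.
#' @return A cohort with the selected rows; metadata unchanged.
#' @export
cohort_rows <- function(x, rows) {
  structure(list(x = x$x[rows, , drop = FALSE], y = x$y[rows],
                 kinds = x$kinds, domains = x$domains),
            class = "cohort")
}

#' Select cohort features
#'
#' @param x a [cohort()].
#' @param cols feature names or column index.
#' @return A cohort restricted to the selected features.
#' @export
cohort_features <- function(x, cols) {
  xm <- x$x[, cols, drop = FALSE]
  structure(list(x = xm, y = x$y,
                 kinds = x$kinds[colnames(xm)], domains = x$domains[colnames(xm)]),
            class = "cohort")
}

#' Read a cohort from CSV
#'
#' Reads a header CSV with one row per subject, applies a column schema
#' mapping each predictor to its kind and domain, and returns a [cohort()].
#' Empty cells and \code{"NA"} become missing values for [impute_knn()].
#'
#' @param path path to a CSV file with a header row.
#' @param schema named list: one entry per predictor column, each a list with
#'   elements \code{kind} and \code{domain}; see [cohort()] for the allowed
#'   values.
#' @param outcome name of the outcome column (default \code{"outcome"}).
#' @return A [cohort()] (possibly with missing feature cells).
#' @export
read_cohort <- function(path, schema, outcome = "outcome") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!outcome %in% names(df)) stop("outcome column '", outcome, "' not found")
  unknown <- setdiff(names(schema), names(df))
  if (length(unknown)) {
    stop("schema names columns absent from the CSV: ",
         paste(unknown, collapse = ", "))
  }
  y <- suppressWarnings(as.numeric(df[[outcome]]))
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome column must be binary 0/1")
  }
  feats <- names(schema)
  x <- as.matrix(df[, feats, drop = FALSE])
  storage.mode(x) <- "double"
  cohort(x, y,
         kinds = vapply(schema, function(s) s$kind, character(1)),
         domains = vapply(schema, function(s) s$domain, character(1)))
}

#' Write a cohort to CSV
#'
#' @param cohort a [cohort()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort$x)
  df$outcome <- cohort$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Schema of a cohort, suitable for [read_cohort()]
#'
#' @param cohort a [cohort()].
#' @return Named list of \code{list(kind =, domain =)} entries.
#' @export
cohort_schema <- function(cohort) {
  stats::setNames(
    lapply(colnames(cohort$x), function(f) {
      list(kind = unname(cohort$kinds[f]), domain = unname(cohort$domains[f]))
    }),
    colnames(cohort$x))
}
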