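#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Template of 21 survey-style predictors spanning the four risk-factor
# domains. Rates and ranges are round numbers typical of U.S. health-survey
# marginals; effects are log-odds weights on internally z-scored features.
cohort_template <- function() {
  data.frame(
    name = c("Sex", "Age", "Education", "Income",
             "HighBP", "HighChol", "CholCheck", "BMI", "Stroke", "Diabetes",
             "Smoker", "PhysActivity", "Fruits", "Veggies", "HvyAlcoholConsump",
             "AnyHealthcare", "NoDocbcCost", "GenHlth", "MentHlth", "PhysHlth",
             "DiffWalk"),
    kind = c("binary", "ordinal", "ordinal", "ordinal",
             "binary", "binary", "binary", "continuous", "binary", "ordinal",
             "binary", "binary", "binary", "binary", "binary",
             "binary", "binary", "ordinal", "continuous", "continuous",
             "binary"),
    domain = c(rep("demographic", 4), rep("clinical", 6),
               rep("behavioral", 5), rep("healthcare", 6)),
    effect = c(0.25, 0.70, -0.10, -0.20,
               0.50, 0.40, 0.05, 0.25, 0.40, 0.40,
               0.35, -0.20, -0.05, -0.05, -0.10,
               0.05, 0.10, 0.60, 0.10, 0.25,
               0.40),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic survey-style cohort
#'
#' Describes a cohort to be generated by [generate_cohort()]: 21 mixed-type
#' predictors (binary, ordinal and continuous, e.g. high blood pressure,
#' general-health score, body-mass index) spread over the demographic,
#' clinical, behavioral and healthcare-access domains, with a binary outcome
#' drawn from a latent logistic risk model whose intercept is calibrated so
#' the expected prevalence matches \code{prevalence}.
#'
#' @param n number of subjects (at least 20).
#' @param prevalence target outcome rate in (0, 1); default 0.0942, the
#'   minority share typical of self-reported coronary heart disease.
#' @param effect_sizes named numeric vector of per-feature log-odds weights
#'   (on z-scored features); defaults to a plausible risk-factor profile.
#'   Use \code{0} for a null cohort.
#' @param noise_sd standard deviation of the latent Gaussian noise added to
#'   the linear predictor (default 1).
#' @param cluster_spec optional list for [generate_clustered()]:
#'   \code{k} (clusters), \code{separation} (centroid shift in SD units),
#'   \code{domain} (one of the four domains or \code{"all"}), and
#'   \code{outcome_or} (length-\code{k} odds multipliers, first = reference).
#' @param seed integer seed fixing the whole generation stream.
#' @return A \code{"cohort_spec"} list.
#' @export
cohort_spec <- function(n, prevalence = 0.0942, effect_sizes = NULL,
                        noise_sd = 1, cluster_spec = NULL, seed = 1L) {
  stopifnot(n >= 20, prevalence > 0, prevalence < 1, noise_sd >= 0)
  tmpl <- cohort_template()
  eff <- stats::setNames(tmpl$effect, tmpl$name)
  if (!is.null(effect_sizes)) {
    if (length(effect_sizes) == 1L && is.null(names(effect_sizes))) {
      eff[] <- effect_sizes
    } else {
      stopifnot(all(names(effect_sizes) %in% tmpl$name))
      eff[names(effect_sizes)] <- effect_sizes
    }
  }
  if (!is.null(cluster_spec)) {
    stopifnot(cluster_spec$k >= 1, cluster_spec$separation >= 0)
    if (cluster_spec$k > n / 10) stop("cluster count k exceeds n/10")
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 effect_sizes = eff, noise_sd = noise_sd,
                 cluster_spec = cluster_spec, seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_features <- function(n) {
  tmpl <- cohort_template()
  x <- matrix(0, n, nrow(tmpl), dimnames = list(NULL, tmpl$name))
  x[, "Sex"] <- stats::rbinom(n, 1, 0.45)
  x[, "Age"] <- sample(1:13, n, replace = TRUE,
                       prob = stats::dnorm(1:13, mean = 8, sd = 3))
  x[, "Education"] <- sample(1:6, n, replace = TRUE,
                             prob = c(0.01, 0.04, 0.10, 0.25, 0.28, 0.32))
  x[, "Income"] <- sample(1:8, n, replace = TRUE,
                          prob = c(0.04, 0.05, 0.06, 0.08, 0.10, 0.14, 0.17, 0.36))
  x[, "HighBP"] <- stats::rbinom(n, 1, 0.43)
  x[, "HighChol"] <- stats::rbinom(n, 1, 0.42)
  x[, "CholCheck"] <- stats::rbinom(n, 1, 0.96)
  x[, "BMI"] <- round(pmin(pmax(stats::rnorm(n, 28.4, 6.6), 12), 60), 1)
  x[, "Stroke"] <- stats::rbinom(n, 1, 0.04)
  x[, "Diabetes"] <- sample(0:2, n, replace = TRUE, prob = c(0.84, 0.02, 0.14))
  x[, "Smoker"] <- stats::rbinom(n, 1, 0.44)
  x[, "PhysActivity"] <- stats::rbinom(n, 1, 0.76)
  x[, "Fruits"] <- stats::rbinom(n, 1, 0.63)
  x[, "Veggies"] <- stats::rbinom(n, 1, 0.81)
  x[, "HvyAlcoholConsump"] <- stats::rbinom(n, 1, 0.06)
  x[, "AnyHealthcare"] <- stats::rbinom(n, 1, 0.95)
  x[, "NoDocbcCost"] <- stats::rbinom(n, 1, 0.08)
  x[, "GenHlth"] <- sample(1:5, n, replace = TRUE,
                           prob = c(0.18, 0.35, 0.30, 0.12, 0.05))
  x[, "MentHlth"] <- round(pmin(stats::rexp(n, 1 / 3.2), 30))
  x[, "PhysHlth"] <- round(pmin(stats::rexp(n, 1 / 4.2), 30))
  x[, "DiffWalk"] <- stats::rbinom(n, 1, 0.17)
  x
}

# Solve the logistic intercept so the mean outcome probability over the
# realised latent scores equals the target prevalence (bisection).
calibrate_intercept <- function(eta, prevalence, tol = 1e-10) {
  f <- function(c0) mean(stats::plogis(c0 + eta)) - prevalence
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) stop("infeasible prevalence after calibration")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return A [cohort()] with attributes \code{"truth"} (a list holding the
#'   effect sizes, calibrated intercept and, if clustered, cluster labels
#'   and planted odds ratios).
#' @examples
#' co <- generate_cohort(cohort_spec(n = 500, seed = 7))
#' mean(co$y)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    tmpl <- cohort_template()
    x <- draw_features(spec$n)
    labels <- NULL
    if (!is.null(spec$cluster_spec)) {
      cs <- spec$cluster_spec
      labels <- sample.int(cs$k, spec$n, replace = TRUE)
      dom_feats <- if (identical(cs$domain, "all") || is.null(cs$domain)) {
        tmpl$name
      } else tmpl$name[tmpl$domain == cs$domain]
      # fixed random centroid directions, scaled by feature spread
      dirs <- matrix(stats::rnorm(cs$k * length(dom_feats)), cs$k)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      sds <- pmax(apply(x[, dom_feats, drop = FALSE], 2, stats::sd), 1e-8)
      for (g in seq_len(cs$k)) {
        rows <- labels == g
        x[rows, dom_feats] <- x[rows, dom_feats] +
          rep(cs$separation * dirs[g, ] * sds, each = sum(rows))
      }
    }
    z <- scale(x)
    z[, attr(z, "scaled:scale") == 0] <- 0
    eta <- drop(z %*% spec$effect_sizes) +
      stats::rnorm(spec$n, sd = spec$noise_sd)
    or_shift <- 0
    if (!is.null(spec$cluster_spec) && !is.null(spec$cluster_spec$outcome_or)) {
      or <- spec$cluster_spec$outcome_or
      stopifnot(length(or) == spec$cluster_spec$k, all(or > 0))
      or_shift <- log(or)[labels]
      eta <- eta + or_shift
    }
    c0 <- calibrate_intercept(eta, spec$prevalence)
    y <- stats::rbinom(spec$n, 1, stats::plogis(c0 + eta))
    co <- cohort(x, y, kinds = tmpl$kind, domains = tmpl$domain)
    attr(co, "truth") <- list(effect_sizes = spec$effect_sizes,
                              intercept = c0,
                              linear_predictor = c0 + eta,
                              cluster_labels = labels,
                              outcome_or = spec$cluster_spec$outcome_or)
    co
  })
}

#' Generate a cohort with planted cluster structure
#'
#' Convenience wrapper around [generate_cohort()] for specs carrying a
#' \code{cluster_spec}; returns the cohort together with the true labels so
#' cluster-recovery and odds-ratio-recovery experiments can score against
#' the truth.
#'
#' @param spec a [cohort_spec()] with non-null \code{cluster_spec}.
#' @return List with elements \code{cohort} and \code{labels} (1-based true
#'   cluster assignment).
#' @export
generate_clustered <- function(spec) {
  stopifnot(!is.null(spec$cluster_spec), spec$cluster_spec$separation > 0)
  co <- generate_cohort(spec)
  list(cohort = co, labels = attr(co, "truth")$cluster_labels)
}
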