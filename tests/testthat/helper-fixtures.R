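# Shared fixtures: small hand-built cohorts and a constant-probability fake
# learner used to probe the combiners.

# a cohort from a plain matrix; all features continuous/clinical by default
mat_cohort <- function(x, y, kinds = NULL, domains = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(kinds)) kinds <- rep("continuous", ncol(x))
  if (is.null(domains)) domains <- rep("clinical", ncol(x))
  cohort(x, y, kinds = kinds, domains = domains)
}

# two-feature cohort whose outcome is a noiseless single threshold on f1
threshold_cohort <- function(n = 200, seed = 1) {
  set.seed(seed)
  x <- cbind(f1 = stats::rnorm(n), f2 = stats::rnorm(n))
  mat_cohort(x, as.integer(x[, "f1"] > 0))
}

# linearly separable two-feature cohort with a margin
separable_cohort <- function(n = 100, gap = 1, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- cbind(f1 = stats::rnorm(n) + ifelse(y == 1, gap, -gap),
             f2 = stats::rnorm(n))
  mat_cohort(x, y)
}

# model that always outputs a fixed probability (for combiner arithmetic)
fixed_prob_model <- function(p) structure(list(p = p), class = "fixedprob")
predict_prob.fixedprob <- function(model, x) {
  rep(model$p, nrow(if (inherits(x, "cohort")) x$x else as.matrix(x)))
}
registerS3method("predict_prob", "fixedprob", predict_prob.fixedprob,
                 envir = asNamespace("chdrisk"))

# hand-built leaf / stump trees in the package's internal node format
leaf_node <- function(p1, n = 10) {
  list(leaf = TRUE, prob = c(1 - p1, p1), n = n, w = n, risk = 0)
}
stump_node <- function(feature, theta, p_left, p_right, n = 10) {
  list(leaf = FALSE, feature = feature, theta = theta, beta = Inf,
       n = n, w = n, risk = 0,
       left = leaf_node(p_left, n / 2), right = leaf_node(p_right, n / 2))
}

tree_model <- function(tree, features) {
  structure(list(trees = list(tree), weights = 1, features = features),
            class = "hirf")
}
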