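two_blob_matrix <- function(n_per = 20, sep = 8, seed = 2) {
  set.seed(seed)
  rbind(matrix(rnorm(n_per * 2), n_per, 2),
        matrix(rnorm(n_per * 2) + sep, n_per, 2))
}

test_that("k-means minimises within-cluster squared distance", {
  x <- two_blob_matrix()
  # k = 1: centroid is the global mean and J the total scatter
  m1 <- kmeans_fit(x, 1, seed = 1, restarts = 2)
  expect_equal(drop(m1$centers), colMeans(x))
  expect_equal(m1$J, sum(scale(x, scale = FALSE)^2))

  # two planted blobs: exact partition, matching brute-force assignment
  m2 <- kmeans_fit(x, 2, seed = 1, restarts = 5)
  expect_equal(adjusted_rand(m2$assignments, rep(1:2, each = 20)), 1)
  d2 <- as.matrix(dist(rbind(x, m2$centers)))[1:40, 41:42]
  expect_identical(m2$assignments, unname(apply(d2, 1, which.min)))

  # Lloyd objective trace is nonincreasing
  set.seed(9)
  xr <- matrix(rnorm(200), 100, 2)
  mr <- kmeans_fit(xr, 4, seed = 3, restarts = 1)
  expect_true(all(diff(mr$J_trace) <= 1e-9))
  expect_error(kmeans_fit(matrix(1, 5, 2), 3), "distinct")
})

test_that("k-means matches the reference implementation on blobs", {
  x <- two_blob_matrix(30, sep = 6, seed = 4)
  ours <- kmeans_fit(x, 2, seed = 1, restarts = 5)
  ref <- kmeans(x, 2, nstart = 5)
  expect_equal(ours$J, ref$tot.withinss, tolerance = 1e-8)
})

test_that("silhouette matches brute-force pairwise computation", {
  x <- two_blob_matrix(15, sep = 5, seed = 3)
  assign <- rep(1:2, each = 15)
  s <- silhouette_score(x, assign)
  # brute force
  D <- as.matrix(dist(x))
  svals <- sapply(1:30, function(i) {
    own <- which(assign == assign[i] & seq_len(30) != i)
    oth <- which(assign != assign[i])
    a <- mean(D[i, own]); b <- mean(D[i, oth])
    (b - a) / max(a, b)
  })
  expect_equal(s, mean(svals), tolerance = 1e-12)
  skip_if_not_installed("cluster")
  ref <- mean(cluster::silhouette(assign, dist(x))[, 3])
  expect_equal(s, ref, tolerance = 1e-12)

  # widely separated tight clusters approach 1
  far <- rbind(matrix(rnorm(20, sd = 1e-3), 10, 2),
               matrix(rnorm(20, sd = 1e-3) + 1e6, 10, 2))
  expect_gt(silhouette_score(far, rep(1:2, each = 10)), 0.999)

  # all points identical: convention 0
  same <- matrix(1, 10, 2)
  expect_equal(silhouette_score(same, rep(1:2, 5)), 0)
  expect_error(silhouette_score(x, rep(1, 30)), "2 clusters")
})

test_that("silhouette-based selection recovers planted blob counts", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40), 20, 2),
             matrix(rnorm(40) + 7, 20, 2),
             matrix(rnorm(40) + c(14, 0), 20, 2))
  sel <- select_k(x, 2:6, seed = 2, restarts = 5)
  expect_equal(sel$k, 3)
  sel2 <- select_k(x, 2:6, seed = 2, restarts = 5)
  expect_identical(sel$profile, sel2$profile)  # deterministic under seed
})

test_that("chi-square association is calibrated and exact on hand tables", {
  # hand 2x2 table against the textbook formula
  assign <- rep(c(0, 1), c(40, 60))
  outcome <- c(rep(c(0, 1), c(30, 10)), rep(c(0, 1), c(20, 40)))
  res <- chisq_association(assign, outcome)
  tab <- table(assign, outcome)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected))
  expect_equal(res$df, 1)

  # perfectly predictive clusters
  res2 <- chisq_association(rep(c(0, 1), c(50, 50)),
                            rep(c(0, 1), c(50, 50)))
  expect_lt(res2$p_value, 1e-10)

  # p uniform under the null
  set.seed(11)
  ps <- replicate(1000, {
    a <- sample(0:2, 120, replace = TRUE)
    y <- sample(0:1, 120, replace = TRUE)
    chisq_association(a, y)$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("cluster-dummy logistic table transforms coefficients to ORs", {
  expect_equal(round(or_from_coef(0, 0.1)$or, 2), 1.00)
  set.seed(13)
  assign <- sample(0:2, 600, replace = TRUE)
  rates <- c(0.1, 0.3, 0.6)
  outcome <- rbinom(600, 1, rates[assign + 1])
  tab <- cluster_logit(assign, outcome)
  expect_equal(nrow(tab), 3)
  # saturated model: fitted cluster probabilities equal empirical rates
  fitted_p <- plogis(c(tab$coef[1], tab$coef[1] + tab$coef[2:3]))
  emp <- tapply(outcome, assign, mean)
  expect_equal(unname(fitted_p), as.vector(emp), tolerance = 1e-8)
  # OR column is the exponentiated coefficient with Wald interval
  expect_equal(tab$or, exp(tab$coef), tolerance = 1e-12)
  expect_equal(tab$ci_lower, exp(tab$coef - 1.96 * tab$std_err))
  # matches glm's Wald table
  ref <- summary(glm(outcome ~ factor(assign), family = binomial()))
  expect_equal(tab$coef, unname(ref$coefficients[, 1]), tolerance = 1e-8)
  expect_equal(tab$std_err, unname(ref$coefficients[, 2]), tolerance = 1e-6)
})

test_that("separated fits are ridge-stabilised rather than divergent", {
  assign <- rep(c(0, 1), c(30, 30))
  outcome <- rep(c(0L, 1L), c(30, 30))  # complete separation
  tab <- cluster_logit(assign, outcome)
  expect_true(attr(tab, "ridged"))
  expect_true(all(is.finite(tab$coef)))
  expect_true(all(is.finite(tab$std_err)))
})

test_that("planted clusters are recovered with restarts", {
  gen <- generate_clustered(cohort_spec(
    n = 600, seed = 15,
    cluster_spec = list(k = 3, separation = 10, domain = "clinical")))
  feats <- names(gen$cohort$domains)[gen$cohort$domains == "clinical"]
  x <- chdrisk:::encode_for_clustering(gen$cohort, feats)
  m <- kmeans_fit(x, 3, seed = 4, restarts = 10)
  expect_gte(adjusted_rand(m$assignments, gen$labels), 0.95)
})

test_that("the domain-wise report covers every domain with valid tables", {
  co <- generate_cohort(cohort_spec(n = 400, prevalence = 0.3, seed = 16))
  rep_ <- risk_cluster_report(co, k_range = 2:4, seed = 3, restarts = 3)
  expect_setequal(names(rep_),
                  c("demographic", "clinical", "behavioral", "healthcare",
                    "full"))
  for (r in rep_) {
    expect_true(r$k >= 2 && r$k <= 4)
    expect_true(r$silhouette >= -1 && r$silhouette <= 1)
    expect_equal(r$chisq$df, r$k - 1)
    expect_equal(nrow(r$logit), r$k)
    expect_equal(r$logit$or, exp(r$logit$coef), tolerance = 1e-10)
  }
})
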