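#' Save / load a fitted model as JSON
#'
#' Models are persisted with \code{jsonlite::serializeJSON}, which keeps R
#' types, attributes and classes exactly, so a reloaded model predicts
#' bit-identically.
#'
#' @param model any fitted model from this package.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  # 17 significant digits give an exact decimal round-trip for doubles
  writeLines(jsonlite::serializeJSON(model, digits = I(17)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Baseline random forest reference configuration
#'
#' Bootstrap trees with \eqn{\sqrt d} feature subsampling and uniform tree
#' weights — [fit_hirf()] without the SMOTE balancing or contribution
#' weighting, used for enhanced-vs-baseline comparisons.
#'
#' @param train a complete [cohort()].
#' @param n_trees,max_depth,min_leaf,seed as in [fit_hirf()].
#' @return A \code{"hirf"} model with uniform weights.
#' @export
fit_rf_baseline <- function(train, n_trees = 200L, max_depth = 8L,
                            min_leaf = 5L, seed = 2025L) {
  d <- ncol(train$x)
  mtry <- max(1L, floor(sqrt(d)))
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(b) {
      rows <- sample.int(nrow(train$x), replace = TRUE)
      boot <- cohort_rows(train, rows)
      grow_tree(boot$x, boot$y, type = "class", max_depth = max_depth,
                min_leaf = min_leaf, mtry = mtry)
    })
  })
  structure(list(trees = trees, weights = rep(1 / n_trees, n_trees),
                 features = colnames(train$x)),
            class = "hirf")
}

default_model_set <- function(n_trees, rounds, svm_budget, seed) {
  list(
    dt = function(tr, va) fit_cart(tr),
    rf = function(tr, va) fit_rf_baseline(tr, n_trees = n_trees, seed = seed),
    gbm = function(tr, va) fit_gradient_boost(tr, va, loss = "logistic",
                                              max_rounds = rounds,
                                              patience = 10L),
    svm = function(tr, va) fit_svm_baseline(tr, seed = seed),
    anrdt = function(tr, va) fit_anrdt(tr, va),
    hirf = function(tr, va) fit_hirf(tr, va, n_trees = n_trees, seed = seed),
    pgbm = function(tr, va) fit_pgbm(tr, va, max_rounds = rounds),
    esvm = function(tr, va) fit_esvm(tr, va, budget = svm_budget, seed = seed)
  )
}

#' Configure a benchmark run
#'
#' @param n synthetic cohort size (before SMOTE).
#' @param seed single global seed propagated to every stochastic stage.
#' @param models character subset of
#'   \code{c("dt","rf","gbm","svm","anrdt","hirf","pgbm","esvm")}.
#' @param ensembles character subset of
#'   \code{c("bagging","adaboost","gboost","stacking","voting","bma")}.
#' @param smote_k,target_ratio SMOTE parameters.
#' @param yamane_e Yamane margin of error used to size the post-balance
#'   subsample (\code{NA} skips subsampling).
#' @param n_trees,rounds,svm_budget model-size knobs.
#' @param folds CV folds for fold-averaged metrics.
#' @param cluster_k_range k-selection range for the subgroup analysis.
#' @param out_dir output directory (created); \code{NULL} disables files.
#' @return A \code{"run_config"} list.
#' @export
benchmark_config <- function(n = 2000L, seed = 1L,
                             models = c("dt", "rf", "gbm", "anrdt", "hirf",
                                        "pgbm"),
                             ensembles = c("bagging", "adaboost", "gboost",
                                           "stacking", "voting", "bma"),
                             smote_k = 5L, target_ratio = 1,
                             yamane_e = NA, n_trees = 50L, rounds = 60L,
                             svm_budget = 6L, folds = 5L,
                             cluster_k_range = 2:6, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the end-to-end benchmark on a synthetic cohort
#'
#' Executes the full comparative protocol: simulate, preprocess,
#' SMOTE-balance the training part, optionally subsample to the Yamane
#' size, 70/15/15 split, fit the selected base learners and ensemble
#' combiners, evaluate each on the held-out test set (confusion-matrix
#' metrics, ROC AUC, average precision) plus fold-averaged CV metrics for
#' base learners, run the domain-wise risk clustering, and rank features by
#' sampled Shapley attributions. All stages derive their randomness from
#' \code{config$seed}, so identical configs reproduce identical outputs.
#'
#' @param config a [benchmark_config()].
#' @return A list: \code{metrics} (per-model test metrics),
#'   \code{cv_metrics}, \code{clusters}, \code{shap_ranking},
#'   \code{timings}; files are written under \code{config$out_dir} when set.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[3]
  timings <- c()
  tic <- function(stage) {
    timings[stage] <<- proc.time()[3] - t0
    t0 <<- proc.time()[3]
  }
  co <- generate_cohort(cohort_spec(config$n, seed = config$seed))
  tic("simulate")
  pp <- preprocess(co)
  tic("preprocess")
  sp <- split_cohort(pp$cohort, seed = config$seed)
  train <- smote_balance(sp$train, k = config$smote_k,
                         target_ratio = config$target_ratio,
                         seed = config$seed)
  if (!is.na(config$yamane_e)) {
    nsub <- yamane_sample_size(nrow(train$x), config$yamane_e)
    if (nsub < nrow(train$x)) {
      train <- stratified_subsample(train, nsub, seed = config$seed)
    }
  }
  tic("resample")
  fitters <- default_model_set(config$n_trees, config$rounds,
                               config$svm_budget, config$seed)
  fitters <- fitters[intersect(config$models, names(fitters))]
  models <- lapply(fitters, function(f) f(train, sp$val))
  tic("train_base")
  base_for_ens <- models
  ens <- list()
  for (e in config$ensembles) {
    ens[[e]] <- switch(
      e,
      bagging = fit_bagging(train, B = 25L, seed = config$seed),
      adaboost = fit_adaboost(train, rounds = config$rounds,
                              seed = config$seed),
      gboost = fit_gradient_boost(train, sp$val, loss = "logistic",
                                  max_rounds = config$rounds,
                                  patience = 10L),
      stacking = fit_stacking(base_for_ens, sp$val),
      voting = fit_voting(base_for_ens),
      bma = fit_bma(base_for_ens, sp$val))
  }
  tic("train_ensembles")
  all_models <- c(models, ens)
  metrics <- do.call(rbind, lapply(names(all_models), function(nm) {
    p <- predict_prob(all_models[[nm]], sp$test)
    cm <- confusion(sp$test$y, p)
    data.frame(model = nm,
               accuracy = accuracy(cm), precision = precision(cm),
               sensitivity = sensitivity(cm), specificity = specificity(cm),
               f1 = f1_score(cm), auc_roc = roc_auc(sp$test$y, p)$auc,
               avg_precision = pr_curve(sp$test$y, p)$average_precision)
  }))
  cvm <- do.call(rbind, lapply(names(fitters), function(nm) {
    cbind(model = nm,
          cv_metric_report(function(co2) fitters[[nm]](co2, sp$val), train,
                           folds = config$folds, seed = config$seed))
  }))
  tic("evaluate")
  clus <- risk_cluster_report(pp$cohort, k_range = config$cluster_k_range,
                              seed = config$seed, restarts = 5L)
  tic("cluster")
  explained <- all_models[[which.max(metrics$auc_roc)]]
  bg_rows <- with_seed(config$seed,
                       sample.int(nrow(train$x), min(50L, nrow(train$x))))
  bg <- train$x[bg_rows, , drop = FALSE]
  ex_rows <- with_seed(config$seed + 1L,
                       sample.int(nrow(sp$test$x), min(20L, nrow(sp$test$x))))
  exps <- lapply(ex_rows, function(i)
    shap_sample(function(m) predict_prob(explained, m), sp$test$x[i, ], bg,
                n_perm = 30L, seed = config$seed + i))
  ranking <- mean_abs_shap(exps)
  tic("explain")
  out <- list(metrics = metrics, cv_metrics = cvm, clusters = clus,
              shap_ranking = ranking, timings = timings,
              preprocess_report = pp$report)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(cvm, file.path(config$out_dir, "cv_metrics.csv"),
                     row.names = FALSE)
    for (dm in names(clus)) {
      if (is.null(clus[[dm]])) next
      utils::write.csv(clus[[dm]]$logit,
                       file.path(config$out_dir,
                                 paste0("clusters_", dm, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(ranking, file.path(config$out_dir, "shap_ranking.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(timings),
                         file.path(config$out_dir, "timings.json"),
                         auto_unbox = TRUE)
  }
  out
}
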