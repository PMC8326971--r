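# Gradient-boosted decision-tree classifier: training, randomized
# hyperparameter search, cross-validation, feature importance.
#
# The backend is xgboost (binary:logistic, exact greedy trees, single
# thread), behind a thin seam: `fit_gbdt` is the only function that touches
# the backend API, so another GBDT implementation can be swapped in without
# disturbing the rest of the pipeline. Hyperparameters use the vocabulary
# common in the GBDT literature and are mapped onto the backend's
# parameters inside `fit_gbdt`.

#' Default GBDT configuration
#'
#' @return Named list: `learning_rate` (0.1), `n_estimators` (200 trees),
#'   `max_depth` (6), `min_child_samples` (5, mapped to minimum child
#'   weight), `feature_fraction` (1 = no column subsampling),
#'   `bagging_fraction` (1 = no row subsampling, which keeps training
#'   invariant under row permutation), `reg_lambda` (1, L2), `reg_alpha`
#'   (0, L1).
#' @export
default_gbdt_config <- function() {
  list(learning_rate = 0.1, n_estimators = 200L, max_depth = 6L,
       min_child_samples = 5, feature_fraction = 1.0, bagging_fraction = 1.0,
       reg_lambda = 1.0, reg_alpha = 0.0)
}

# Documented randomized-search space; sampled log-uniformly where noted.
GBDT_SEARCH_SPACE <- list(
  learning_rate     = c(0.02, 0.3),    # log-uniform
  n_estimators      = c(100L, 400L),
  max_depth         = c(3L, 8L),
  min_child_samples = c(2, 30),
  feature_fraction  = c(0.6, 1.0),
  bagging_fraction  = c(0.6, 1.0),
  reg_lambda        = c(1e-3, 10),     # log-uniform
  reg_alpha         = c(1e-3, 1)       # log-uniform
)

.sample_config <- function() {
  sp <- GBDT_SEARCH_SPACE
  logu <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  list(learning_rate = logu(sp$learning_rate),
       n_estimators = sample(seq(sp$n_estimators[1], sp$n_estimators[2], by = 50L), 1L),
       max_depth = sample(sp$max_depth[1]:sp$max_depth[2], 1L),
       min_child_samples = stats::runif(1, sp$min_child_samples[1], sp$min_child_samples[2]),
       feature_fraction = stats::runif(1, sp$feature_fraction[1], sp$feature_fraction[2]),
       bagging_fraction = stats::runif(1, sp$bagging_fraction[1], sp$bagging_fraction[2]),
       reg_lambda = logu(sp$reg_lambda),
       reg_alpha = logu(sp$reg_alpha))
}

#' Fit the gradient-boosted classifier
#'
#' Deterministic given (data, config, seed): single-threaded exact tree
#' construction with a fixed backend seed.
#'
#' @param ds A `labeled_dataset` (or list with elements `x` matrix, `y` 0/1).
#' @param config Hyperparameters, see [default_gbdt_config()].
#' @param seed Integer seed for the backend RNG.
#' @return A `gbdt_classifier`: booster, feature schema, config, seed and the
#'   fixed 0.5 decision threshold.
#' @export
fit_gbdt <- function(ds, config = default_gbdt_config(), seed = 1L) {
  if (inherits(ds, "labeled_dataset")) {
    x <- dataset_matrix(ds); y <- dataset_labels(ds)
  } else {
    x <- ds$x; y <- as.integer(ds$y)
  }
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  if (min(table(y)) < 2L) stop("need at least 2 rows per class")
  dtrain <- xgboost::xgb.DMatrix(x, label = y, missing = NA)
  params <- list(objective = "binary:logistic", eval_metric = "logloss",
                 tree_method = "exact", nthread = 1L, seed = as.integer(seed),
                 eta = config$learning_rate,
                 max_depth = as.integer(config$max_depth),
                 min_child_weight = config$min_child_samples,
                 colsample_bytree = config$feature_fraction,
                 subsample = config$bagging_fraction,
                 lambda = config$reg_lambda, alpha = config$reg_alpha)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = as.integer(config$n_estimators),
                                verbose = 0)
  structure(list(booster = booster, feature_names = colnames(x),
                 config = config, seed = as.integer(seed), threshold = 0.5),
            class = "gbdt_classifier")
}

#' @export
print.gbdt_classifier <- function(x, ...) {
  cat("<gbdt_classifier> ", length(x$feature_names), " features, ",
      x$config$n_estimators, " trees, threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

.check_schema <- function(clf, x) {
  have <- colnames(x)
  if (!identical(have, clf$feature_names)) {
    missing <- setdiff(clf$feature_names, have)
    extra <- setdiff(have, clf$feature_names)
    stop("feature schema mismatch",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         if (!length(missing) && !length(extra)) "; columns out of order")
  }
}

#' Predict the probability of splicing pathogenicity
#'
#' Returns the probability of the pathogenic class; 0 means no predicted
#' effect on splicing, 1 a certain effect. The classification rule is
#' `p >= 0.5` = splicing-affecting.
#'
#' @param clf A `gbdt_classifier`.
#' @param fv A named feature vector, feature matrix, or `labeled_dataset`;
#'   schema must match the classifier's.
#' @return Numeric probabilities in `[0, 1]`.
#' @export
predict_proba <- function(clf, fv) {
  if (inherits(fv, "labeled_dataset")) fv <- dataset_matrix(fv)
  if (is.null(dim(fv))) fv <- matrix(fv, nrow = 1L, dimnames = list(NULL, names(fv)))
  .check_schema(clf, fv)
  predict(clf$booster, xgboost::xgb.DMatrix(fv, missing = NA))
}

#' Classify from a probability
#' @param p Probability vector.
#' @param threshold Decision threshold, default 0.5 (inclusive).
#' @return Character vector `"splicing-affecting"` / `"splicing-insensitive"`.
#' @export
classify_proba <- function(p, threshold = 0.5) {
  ifelse(p >= threshold, "splicing-affecting", "splicing-insensitive")
}

#' Ranked feature importances
#'
#' Gain- (default) or split-based importances from the fitted ensemble,
#' descending, with ties broken lexicographically by feature name. Features
#' never used by any tree get importance 0.
#'
#' @param clf A `gbdt_classifier`.
#' @param top_n Number of features to return; larger than the schema returns
#'   the full list.
#' @param type `"gain"` or `"split"`.
#' @return data.frame with columns `feature`, `importance`.
#' @export
feature_importance <- function(clf, top_n = 10L, type = c("gain", "split")) {
  type <- match.arg(type)
  imp <- xgboost::xgb.importance(model = clf$booster)
  vals <- stats::setNames(rep(0, length(clf$feature_names)), clf$feature_names)
  if (!is.null(imp) && nrow(imp) > 0L) {
    col <- if (type == "gain") imp$Gain else imp$Frequency
    vals[imp$Feature] <- col
  }
  df <- data.frame(feature = names(vals), importance = unname(vals),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$importance, df$feature), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_n)
}

#' Cross-validate the classifier under a split plan
#'
#' For each of the plan's folds, fits on the remaining folds and scores the
#' held-out fold; reports per-fold confusion metrics, ROC and PR curves, and
#' their across-fold means and standard deviations.
#'
#' @param ds A `labeled_dataset`.
#' @param plan A `split_plan` (its training keys are used; folds must number
#'   at least 2).
#' @param config GBDT hyperparameters.
#' @param seed Backend seed for each fold fit.
#' @return A `cv_result`: `fold_metrics` (list of `metrics_report`),
#'   `fold_auroc`, `fold_aupr`, `roc_curves`, `pr_curves`,
#'   `mean_metrics`/`sd_metrics` (named vectors over the seven measures),
#'   `mean_auroc`, `mean_aupr`, `fold_predictions`.
#' @export
cross_validate <- function(ds, plan, config = default_gbdt_config(), seed = 1L) {
  train <- as.data.frame(ds)[ds$key %in% plan$train_keys, , drop = FALSE]
  fold_id <- unname(plan$fold[train$key])
  n_folds <- plan$n_folds
  fold_metrics <- vector("list", n_folds)
  roc_curves <- vector("list", n_folds)
  pr_curves <- vector("list", n_folds)
  fold_auroc <- numeric(n_folds); fold_aupr <- numeric(n_folds)
  preds <- vector("list", n_folds)
  fn <- attr(ds, "feature_names")
  for (f in seq_len(n_folds)) {
    tr <- train[fold_id != f, , drop = FALSE]
    te <- train[fold_id == f, , drop = FALSE]
    if (length(unique(te$label)) < 2L || length(unique(tr$label)) < 2L) {
      stop("fold ", f, " has a single class; refit the split with another seed")
    }
    clf <- fit_gbdt(list(x = as.matrix(tr[, fn]), y = tr$label), config, seed)
    p <- predict(clf$booster,
                 xgboost::xgb.DMatrix(as.matrix(te[, fn]), missing = NA))
    fold_metrics[[f]] <- compute_metrics(confusion_from_predictions(te$label, p))
    roc <- roc_curve(te$label, p); pr <- pr_curve(te$label, p)
    roc_curves[[f]] <- roc; pr_curves[[f]] <- pr
    fold_auroc[f] <- roc$auroc; fold_aupr[f] <- pr$aupr
    preds[[f]] <- data.frame(key = te$key, label = te$label, prob = p,
                             fold = f, stringsAsFactors = FALSE)
  }
  mm <- vapply(METRIC_NAMES, function(m) {
    v <- vapply(fold_metrics, function(fm) fm[[m]], numeric(1))
    mean(v[!is.na(v)])                       # undefined folds excluded, logged
  }, numeric(1))
  sdm <- vapply(METRIC_NAMES, function(m) {
    v <- vapply(fold_metrics, function(fm) fm[[m]], numeric(1))
    stats::sd(v[!is.na(v)])
  }, numeric(1))
  n_undef <- sum(vapply(fold_metrics, function(fm) length(fm$undefined), integer(1)))
  if (n_undef > 0L) message(n_undef, " undefined fold measure(s) excluded from means")
  structure(list(fold_metrics = fold_metrics, fold_auroc = fold_auroc,
                 fold_aupr = fold_aupr, roc_curves = roc_curves,
                 pr_curves = pr_curves, mean_metrics = mm, sd_metrics = sdm,
                 mean_auroc = mean(fold_auroc), mean_aupr = mean(fold_aupr),
                 fold_predictions = do.call(rbind, preds),
                 n_folds = n_folds, config = config, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$n_folds, "-fold CV: AUROC ",
      report_round(x$mean_auroc), ", AUPR ", report_round(x$mean_aupr), "\n",
      sep = "")
  print(report_round(x$mean_metrics))
  invisible(x)
}

#' Randomized hyperparameter search
#'
#' Samples `budget` configurations from the documented search space
#' (`learning_rate`, `n_estimators`, `max_depth`, `min_child_samples`,
#' `feature_fraction`, `bagging_fraction`, `reg_lambda`, `reg_alpha`),
#' always evaluates the default configuration alongside them, and returns the
#' configuration maximizing mean CV AUROC. Deterministic given `seed`.
#'
#' @param ds A `labeled_dataset`.
#' @param budget Number of sampled trials (>= 1; 0 returns the defaults with
#'   a warning).
#' @param seed Integer seed driving both sampling and fold construction.
#' @param n_folds CV folds per trial, default 5.
#' @return List with `config` (best), `auroc` (its mean CV AUROC) and
#'   `history` (data.frame of all trials; trial 0 is the default config).
#' @export
tune_hyperparameters <- function(ds, budget, seed = 1L, n_folds = 5L) {
  if (budget == 0L) {
    warning("budget = 0: returning default configuration unevaluated")
    return(list(config = default_gbdt_config(), auroc = NA_real_,
                history = data.frame()))
  }
  plan <- benchmark_split(ds, character(0), seed = seed, n_folds = n_folds)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trials <- c(list(default_gbdt_config()),
              replicate(budget, .sample_config(), simplify = FALSE))
  auroc <- vapply(trials, function(cfg) {
    cross_validate(ds, plan, cfg, seed = seed)$mean_auroc
  }, numeric(1))
  hist <- cbind(data.frame(trial = seq_along(trials) - 1L, auroc = auroc),
                do.call(rbind, lapply(trials, as.data.frame)))
  best <- which.max(auroc)                     # first max: default wins ties
  list(config = trials[[best]], auroc = auroc[best], history = hist)
}

# ---- persistence -------------------------------------------------------------

#' Save / load a trained classifier
#'
#' The model directory holds the backend-native ensemble file
#' (`ensemble.ubj`), the feature schema (`schema.json`) and the training
#' configuration (`config.json`). A reloaded model predicts identically.
#'
#' @param clf A `gbdt_classifier`.
#' @param dir Directory path (created if needed).
#' @return `load_classifier`: the restored `gbdt_classifier`.
#' @export
save_classifier <- function(clf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(clf$booster, file.path(dir, "ensemble.ubj"))
  jsonlite::write_json(
    list(schema = "acceptorvar-model-1", feature_names = clf$feature_names,
         threshold = clf$threshold, seed = clf$seed),
    file.path(dir, "schema.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(clf$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  sj <- jsonlite::read_json(file.path(dir, "schema.json"), simplifyVector = TRUE)
  if (!identical(sj$schema, "acceptorvar-model-1")) {
    stop("unknown model schema in ", dir)
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  structure(list(booster = xgboost::xgb.load(file.path(dir, "ensemble.ubj")),
                 feature_names = sj$feature_names, config = cfg,
                 seed = sj$seed, threshold = sj$threshold),
            class = "gbdt_classifier")
}
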