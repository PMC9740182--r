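#' Random train/holdout split
#'
#' Simple (non-stratified) random assignment of `round(train_fraction * n)`
#' subjects to training (round-half-up), the remainder to the holdout.
#' Deterministic under the seed; with 486 subjects at the default fraction
#' the split is 389 train / 97 holdout.
#'
#' @param ids Subject identifiers.
#' @param labels Class labels, same order (recorded, not used for
#'   assignment).
#' @param train_fraction Training fraction (default 0.8).
#' @param seed Integer seed.
#'
#' @return List of class `split_spec` with `train_ids`, `holdout_ids` and
#'   the per-partition case counts.
#' @export
split_subjects <- function(ids, labels, train_fraction = 0.8, seed = 1L) {
  n <- length(ids)
  if (n < 10) stop("need at least 10 subjects to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly inside (0, 1)")
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  if (n_train < 1 || n_train >= n)
    stop("split leaves an empty partition")
  set.seed(as.integer(seed))
  tr <- sort(sample.int(n, n_train))
  structure(list(n_total = n, train_fraction = train_fraction,
                 seed = as.integer(seed),
                 train_ids = ids[tr], holdout_ids = ids[-tr],
                 train_cases = sum(labels[tr] == "case"),
                 holdout_cases = sum(labels[-tr] == "case")),
            class = "split_spec")
}

#' Screen features on the training set
#'
#' Transparent stand-in for a proprietary feature subset: features are
#' ranked by their training-set-only association q-value (ties by p), and
#' the top `k` are retained. Holdout rows must not be present in `table`;
#' the caller passes training rows only, so no holdout information can
#' leak into the ranking.
#'
#' @param table Normalised feature table restricted to training subjects.
#' @param subjects Subject metadata (see [associate()]).
#' @param k Number of features to keep (default 64); must not exceed the
#'   number of usable features.
#'
#' @return Character vector of selected feature ids, with the training
#'   association scan attached as attribute `scan`.
#' @export
screen_features <- function(table, subjects, k = 64L) {
  scan <- associate(table, subjects)
  usable <- scan[is.na(scan$flag), ]
  if (k > nrow(usable))
    stop("k = ", k, " exceeds the ", nrow(usable), " usable features")
  ord <- order(usable$q, usable$p)
  sel <- usable$feature_id[ord][seq_len(k)]
  attr(sel, "scan") <- scan
  sel
}

# Hyperparameter search space for the booster (log-uniform learning rate).
mbo_space <- function() {
  list(eta = c(log(0.01), log(0.3)),          # sampled on log scale
       max_depth = c(2, 8),                   # integer
       min_child_weight = c(1, 10),
       subsample = c(0.5, 1),
       colsample_bytree = c(0.5, 1))
}

decode_design <- function(u, space) {
  data.frame(
    eta = exp(space$eta[1] + u[, 1] * diff(space$eta)),
    max_depth = as.integer(round(space$max_depth[1] +
                                   u[, 2] * diff(space$max_depth))),
    min_child_weight = space$min_child_weight[1] +
      u[, 3] * diff(space$min_child_weight),
    subsample = space$subsample[1] + u[, 4] * diff(space$subsample),
    colsample_bytree = space$colsample_bytree[1] +
      u[, 5] * diff(space$colsample_bytree))
}

cv_auc <- function(cand, dtrain, folds, seed, max_rounds = 300L) {
  params <- xgboost::xgb.params(
    objective = "binary:logistic", eval_metric = "auc", nthread = 1,
    seed = seed, eta = cand$eta, max_depth = cand$max_depth,
    min_child_weight = cand$min_child_weight, subsample = cand$subsample,
    colsample_bytree = cand$colsample_bytree)
  cv <- xgboost::xgb.cv(params = params, data = dtrain,
                        nrounds = max_rounds, folds = folds,
                        early_stopping_rounds = 25L, verbose = 0)
  log <- cv$evaluation_log
  best <- which.max(log$test_auc_mean)
  list(auc = log$test_auc_mean[best], nrounds = log$iter[best])
}

#' Tune a gradient-boosted classifier by model-based optimisation
#'
#' Surrogate-assisted search over the booster's hyperparameter space
#' (learning rate, tree depth, min child weight, row and column
#' subsampling; boosting rounds chosen by early stopping inside the
#' cross-validation): a Latin-hypercube initial design, then
#' expected-improvement proposals from a random-forest surrogate of the
#' cross-validated AUC, for `budget` evaluations in total. The best
#' configuration is refit on the full training set at its best round count.
#'
#' @param x Numeric feature matrix (training subjects x screened features).
#' @param y Binary labels (1 = case).
#' @param folds Number of cross-validation folds (default 5).
#' @param budget Total number of configurations evaluated (default 50; the
#'   original procedure's budget of 1000 is available by setting it so).
#' @param seed Integer seed controlling fold assignment, the design and the
#'   booster.
#'
#' @return List of class `tuned_model` with `booster`, `best_params`,
#'   `best_cv_auc`, `nrounds` and the search `history`.
#' @export
tune_and_fit <- function(x, y, folds = 5L, budget = 50L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("labels are single-class")
  if (nrow(x) < folds * 5)
    stop("need at least ", folds * 5, " training subjects for ", folds,
         "-fold tuning")
  if (budget < 1) stop("budget must be at least 1")
  set.seed(as.integer(seed))
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  fold_id <- sample(rep_len(seq_len(folds), nrow(x)))
  fold_list <- split(seq_len(nrow(x)), fold_id)
  space <- mbo_space()

  n_init <- max(1L, min(budget, ceiling(budget / 3), 10L))
  design <- decode_design(lhs::randomLHS(n_init, 5L), space)
  history <- design
  history$auc <- NA_real_
  history$nrounds <- NA_integer_
  for (i in seq_len(nrow(history))) {
    r <- cv_auc(history[i, ], dtrain, fold_list, seed)
    history$auc[i] <- r$auc
    history$nrounds[i] <- r$nrounds
  }

  while (nrow(history) < budget) {
    cand <- decode_design(matrix(runif(200 * 5), 200), space)
    rf <- ranger::ranger(auc ~ eta + max_depth + min_child_weight +
                           subsample + colsample_bytree,
                         data = history[, c(names(cand), "auc")],
                         num.trees = 200, seed = seed)
    pred_all <- predict(rf, cand, predict.all = TRUE)$predictions
    mu <- rowMeans(pred_all)
    sdev <- apply(pred_all, 1, sd)
    best <- max(history$auc)
    z <- (mu - best) / pmax(sdev, 1e-9)
    ei <- (mu - best) * pnorm(z) + pmax(sdev, 1e-9) * stats::dnorm(z)
    pick <- cand[which.max(ei), , drop = FALSE]
    r <- cv_auc(pick, dtrain, fold_list, seed)
    pick$auc <- r$auc
    pick$nrounds <- r$nrounds
    history <- rbind(history, pick)
  }

  ibest <- which.max(history$auc)
  bp <- history[ibest, ]
  params <- xgboost::xgb.params(
    objective = "binary:logistic", nthread = 1, seed = seed,
    eta = bp$eta, max_depth = bp$max_depth,
    min_child_weight = bp$min_child_weight, subsample = bp$subsample,
    colsample_bytree = bp$colsample_bytree)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = max(bp$nrounds, 1L), verbose = 0)
  structure(list(booster = booster,
                 best_params = bp[, setdiff(names(bp), c("auc", "nrounds"))],
                 best_cv_auc = bp$auc, nrounds = bp$nrounds,
                 history = history, seed = as.integer(seed)),
            class = "tuned_model")
}

#' Predict case scores from a tuned model
#'
#' @param model A `tuned_model`.
#' @param x Feature matrix with the training columns.
#' @return Numeric vector of predicted case probabilities.
#' @export
predict_scores <- function(model, x) {
  as.numeric(predict(model$booster,
                     xgboost::xgb.DMatrix(as.matrix(x), nthread = 1)))
}
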