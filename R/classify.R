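.positive <- "ADHD"
.ntree_grid <- c(1L, 5L, 10L, 20L, 30L, 50L)

#' The 17 evaluated feature combinations
#'
#' The 11 single descriptors plus six composites: thigh-related (thigh
#' length + angle), shoulder-related (both shoulder lengths + angles),
#' hip-related (both hip lengths + angles), length-related (all 5 lengths),
#' angle-related (all 6 angles) and all 11 descriptors.
#'
#' @return Named list of character vectors of \code{var_*} column names.
#' @export
feature_combinations <- function() {
  singles <- list(
    right_shoulder_length = "var_l_1_2",
    left_shoulder_length  = "var_l_1_5",
    right_hip_length      = "var_l_8_9",
    left_hip_length       = "var_l_8_12",
    thigh_length          = "var_l_9_10",
    right_shoulder_angle  = "var_th_1_2",
    left_shoulder_angle   = "var_th_1_5",
    right_hip_angle       = "var_th_8_9",
    left_hip_angle        = "var_th_8_12",
    thigh_angle           = "var_th_9_10",
    trunk_angle           = "var_th_8_1")
  c(singles, list(
    thigh_related    = c("var_l_9_10", "var_th_9_10"),
    shoulder_related = c("var_l_1_2", "var_l_1_5", "var_th_1_2", "var_th_1_5"),
    hip_related      = c("var_l_8_9", "var_l_8_12", "var_th_8_9", "var_th_8_12"),
    length_related   = c("var_l_1_2", "var_l_1_5", "var_l_8_9", "var_l_8_12",
                         "var_l_9_10"),
    angle_related    = c("var_th_1_2", "var_th_1_5", "var_th_8_9", "var_th_8_12",
                         "var_th_9_10", "var_th_8_1"),
    all              = feature_names()))
}

.classifier_families <- c("adaboost", "decision_tree", "knn", "random_forest",
                          "svm", "xgboost")

.rpart_control <- function(maxdepth) {
  rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 2L,
                       minbucket = 1L, xval = 0L, maxcompete = 0L,
                       maxsurrogate = 0L, usesurrogate = 0L)
}

# ---- AdaBoost.M1 with CART stumps -------------------------------------------

#' Fit an AdaBoost.M1 ensemble of CART stumps
#'
#' Discrete AdaBoost.M1 for two classes: depth-limited CART trees (stumps by
#' default) are fitted to reweighted data; each round multiplies the weights
#' of misclassified samples by exp(alpha) with
#' alpha = log((1 - err) / err). Boosting stops early when a round's
#' weighted error reaches 0 (perfect stump) or 0.5 (no usable learner).
#'
#' @param X Data frame or matrix of predictors.
#' @param y Two-level factor of group labels.
#' @param n_estimators Maximum number of boosting rounds.
#' @param maxdepth Depth of each weak learner (default 1 = stump).
#' @return Object of class \code{adaboost} (trees, alphas, class levels).
#' @export
fit_adaboost <- function(X, y, n_estimators, maxdepth = 1L) {
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2L, n_estimators >= 1L)
  d <- as.data.frame(X)
  d$.y <- y
  n <- nrow(d)
  w <- rep(1 / n, n)
  ctrl <- .rpart_control(maxdepth)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    case_w <- w * n
    fit <- rpart::rpart(.y ~ ., data = d, weights = case_w, method = "class",
                        control = ctrl)
    pred <- predict(fit, d, type = "class")
    mis <- pred != y
    err <- sum(w[mis])
    if (err >= 0.5 && length(trees) > 0L) break
    err_c <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- log((1 - err_c) / err_c)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 0 || err >= 0.5) break
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas, levels = levels(y)),
            class = "adaboost")
}

.adaboost_votes <- function(model, X) {
  # n x m matrix: does weak learner m vote for the positive class?
  d <- as.data.frame(X)
  v <- vapply(model$trees,
              function(tr) predict(tr, d, type = "class") == .positive,
              logical(nrow(d)))
  matrix(v, nrow = nrow(d))
}

#' Predict from an AdaBoost ensemble
#'
#' @param model An \code{adaboost} fit.
#' @param X New data.
#' @param n_trees Use only the first \code{n_trees} rounds (default: all);
#'   capped at the rounds actually fitted.
#' @return List with \code{class} (factor) and \code{score} (weighted vote
#'   fraction for the positive class in [0, 1]; class = positive when
#'   score >= 0.5).
#' @export
predict_adaboost <- function(model, X, n_trees = NULL) {
  m <- length(model$trees)
  k <- if (is.null(n_trees)) m else min(n_trees, m)
  votes <- .adaboost_votes(model, X)[, seq_len(k), drop = FALSE]
  a <- model$alphas[seq_len(k)]
  if (sum(a) <= 0) a <- rep(1, k)
  score <- as.vector(votes %*% a) / sum(a)
  .class_from_score(score, model$levels)
}

.class_from_score <- function(score, levels) {
  neg <- setdiff(levels, .positive)[1]
  cls <- factor(ifelse(score >= 0.5, .positive, neg), levels = levels)
  list(class = cls, score = score)
}

# ---- per-family specs -------------------------------------------------------

.acc <- function(pred, truth) mean(pred == truth)

.spec_adaboost <- function() {
  grid <- data.frame(n_estimators = .ntree_grid)
  list(
    family = "adaboost", grid = grid,
    eval_fold = function(Xtr, ytr, Xva, yva) {
      model <- fit_adaboost(Xtr, ytr, max(grid$n_estimators))
      votes <- .adaboost_votes(model, Xva)
      a <- model$alphas
      num <- votes %*% (a * upper.tri(diag(length(a)), diag = TRUE))
      den <- cumsum(a)
      vapply(seq_len(nrow(grid)), function(g) {
        k <- min(grid$n_estimators[g], length(a))
        .acc(.class_from_score(num[, k] / den[k], model$levels)$class, yva)
      }, numeric(1))
    },
    fit = function(X, y, params) fit_adaboost(X, y, params$n_estimators),
    predict = function(model, X) predict_adaboost(model, X))
}

.spec_decision_tree <- function() {
  grid <- data.frame(max_depth = c(1L, 2L, 3L, 5L, 7L))
  fit1 <- function(X, y, depth) {
    d <- as.data.frame(X); d$.y <- droplevels(as.factor(y))
    rpart::rpart(.y ~ ., data = d, method = "class", control = .rpart_control(depth))
  }
  pred1 <- function(model, X) {
    p <- predict(model, as.data.frame(X), type = "prob")
    .class_from_score(p[, .positive], colnames(p))
  }
  list(
    family = "decision_tree", grid = grid,
    eval_fold = function(Xtr, ytr, Xva, yva)
      vapply(grid$max_depth, function(depth)
        .acc(pred1(fit1(Xtr, ytr, depth), Xva)$class, yva), numeric(1)),
    fit = function(X, y, params) fit1(X, y, params$max_depth),
    predict = pred1)
}

.spec_knn <- function() {
  grid <- data.frame(n_neighbors = 1:3)
  pred1 <- function(model, X) {
    p <- class::knn(model$X, as.matrix(X), model$y, k = model$k, prob = TRUE)
    win <- attr(p, "prob")
    score <- ifelse(p == .positive, win, 1 - win)
    list(class = factor(p, levels = levels(model$y)), score = score)
  }
  list(
    family = "knn", grid = grid,
    eval_fold = function(Xtr, ytr, Xva, yva) {
      vapply(grid$n_neighbors, function(k) {
        p <- class::knn(as.matrix(Xtr), as.matrix(Xva), droplevels(as.factor(ytr)), k = k)
        .acc(p, yva)
      }, numeric(1))
    },
    fit = function(X, y, params)
      list(X = as.matrix(X), y = droplevels(as.factor(y)), k = params$n_neighbors),
    predict = pred1)
}

.ranger_seed <- function() sample.int(.Machine$integer.max, 1L)

.spec_random_forest <- function() {
  grid <- expand.grid(max_features = 1:3, max_depth = c(1L, 2L, 3L, 5L, 7L),
                      n_estimators = .ntree_grid)
  fit1 <- function(X, y, mf, md, nt) {
    ranger::ranger(x = as.data.frame(X), y = droplevels(as.factor(y)),
                   num.trees = nt, mtry = min(mf, ncol(as.data.frame(X))),
                   max.depth = md, probability = TRUE,
                   num.threads = 1L, seed = .ranger_seed())
  }
  prob_pos <- function(model, X) {
    p <- predict(model, data = as.data.frame(X), num.threads = 1L)$predictions
    p[, .positive]
  }
  list(
    family = "random_forest", grid = grid,
    eval_fold = function(Xtr, ytr, Xva, yva) {
      acc <- numeric(nrow(grid))
      lv <- levels(droplevels(as.factor(ytr)))
      Xva <- as.data.frame(Xva)
      # trees x checkpoint indicator: tree t contributes to the first-k-trees
      # forest when t <= k
      ind <- outer(seq_len(max(.ntree_grid)), .ntree_grid, `<=`) + 0
      # clipped mtry collapses duplicate grid rows for narrow combinations
      mtry_eff <- pmin(grid$max_features, ncol(Xva))
      combos <- unique(data.frame(mtry = mtry_eff, max_depth = grid$max_depth))
      for (i in seq_len(nrow(combos))) {
        mf <- combos$mtry[i]; md <- combos$max_depth[i]
        model <- fit1(Xtr, ytr, mf, md, max(.ntree_grid))
        # per-tree class probabilities: the probability forest of the first
        # k trees is exactly their mean
        pa <- predict(model, data = Xva, num.threads = 1L,
                      predict.all = TRUE)$predictions
        pos_col <- which(model$forest$levels == .positive)
        score <- (pa[, pos_col, ] %*% ind) / rep(.ntree_grid, each = nrow(Xva))
        for (g in seq_along(.ntree_grid)) {
          nt <- .ntree_grid[g]
          rows <- mtry_eff == mf & grid$max_depth == md & grid$n_estimators == nt
          acc[rows] <- .acc(.class_from_score(score[, g], lv)$class, yva)
        }
      }
      acc
    },
    fit = function(X, y, params)
      fit1(X, y, params$max_features, params$max_depth, params$n_estimators),
    predict = function(model, X) {
      score <- prob_pos(model, X)
      .class_from_score(score, model$forest$levels)
    })
}

.spec_svm <- function() {
  grid <- expand.grid(gamma = c(50, 100, 300, 500), C = c(0.001, 0.01, 0.1, 1))
  fit1 <- function(X, y, gamma, C) {
    X <- as.matrix(X)
    e1071::svm(x = X, y = droplevels(as.factor(y)), type = "C-classification",
               kernel = "radial", gamma = gamma, cost = C,
               scale = apply(X, 2L, stats::sd) > 0)
  }
  pred1 <- function(model, X) {
    p <- predict(model, as.matrix(X), decision.values = TRUE)
    dv <- attr(p, "decision.values")
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    score <- if (identical(first, .positive)) dv[, 1] else -dv[, 1]
    list(class = p, score = unname(score))
  }
  list(
    family = "svm", grid = grid,
    eval_fold = function(Xtr, ytr, Xva, yva)
      vapply(seq_len(nrow(grid)), function(g)
        .acc(predict(fit1(Xtr, ytr, grid$gamma[g], grid$C[g]), as.matrix(Xva)), yva),
        numeric(1)),
    fit = function(X, y, params) fit1(X, y, params$gamma, params$C),
    predict = pred1)
}

.spec_xgboost <- function() {
  grid <- expand.grid(learning_rate = c(0.1, 0.2, 0.3),
                      max_depth = c(1L, 2L, 3L, 5L, 7L),
                      n_estimators = .ntree_grid)
  dmat <- function(X, y = NULL) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (is.null(y)) xgboost::xgb.DMatrix(X, nthread = 1L)
    else xgboost::xgb.DMatrix(X, label = as.integer(y == .positive), nthread = 1L)
  }
  fit1 <- function(X, y, eta, md, nrounds) {
    lv <- levels(droplevels(as.factor(y)))
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = eta, max_depth = md,
                    nthread = 1L, eval_metric = "logloss"),
      data = dmat(X, y), nrounds = nrounds, verbose = 0)
    list(booster = booster, levels = lv)
  }
  pred1 <- function(model, X, k = NULL) {
    d <- dmat(X)
    score <- if (is.null(k)) predict(model$booster, d)
             else predict(model$booster, d, iterationrange = c(1L, k))
    .class_from_score(score, model$levels)
  }
  list(
    family = "xgboost", grid = grid,
    eval_fold = function(Xtr, ytr, Xva, yva) {
      acc <- numeric(nrow(grid))
      lv <- levels(droplevels(as.factor(ytr)))
      dtr <- dmat(Xtr, ytr)
      dva <- dmat(Xva)
      combos <- unique(grid[, c("learning_rate", "max_depth")])
      for (i in seq_len(nrow(combos))) {
        eta <- combos$learning_rate[i]; md <- combos$max_depth[i]
        booster <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = eta, max_depth = md,
                        nthread = 1L, eval_metric = "logloss"),
          data = dtr, nrounds = max(.ntree_grid), verbose = 0)
        for (nt in .ntree_grid) {
          score <- predict(booster, dva, iterationrange = c(1L, nt))
          rows <- grid$learning_rate == eta & grid$max_depth == md &
                  grid$n_estimators == nt
          acc[rows] <- .acc(.class_from_score(score, lv)$class, yva)
        }
      }
      acc
    },
    fit = function(X, y, params)
      fit1(X, y, params$learning_rate, params$max_depth, params$n_estimators),
    predict = function(model, X) pred1(model, X))
}

#' Classifier specifications with their tuning grids
#'
#' Six families: AdaBoost on CART stumps, CART decision tree, k-nearest
#' neighbors, random forest, RBF-kernel SVM and gradient-boosted trees, each
#' with its fixed hyperparameter grid (n-estimators {1,5,10,20,30,50};
#' tree max-depth {1,2,3,5,7}; n-neighbors {1,2,3}; forest
#' max-features {1,2,3} x max-depth {1,2,3,5,7} x n-estimators; SVM
#' gamma {50,100,300,500} x C {0.001,0.01,0.1,1}; boosting learning-rate
#' {0.1,0.2,0.3} x max-depth x n-estimators). Grids are serialized in each
#' spec (\code{$grid}) for audit; grid row order is the documented tie-break
#' order (first listed value varies fastest).
#'
#' @param families Subset of
#'   \code{c("adaboost","decision_tree","knn","random_forest","svm","xgboost")}.
#' @return Named list of specs; each spec has \code{family}, \code{grid} and
#'   the fit/predict hooks used by \code{\link{tune_and_fit}}.
#' @export
classifier_specs <- function(families = .classifier_families) {
  families <- match.arg(families, .classifier_families, several.ok = TRUE)
  makers <- list(adaboost = .spec_adaboost, decision_tree = .spec_decision_tree,
                 knn = .spec_knn, random_forest = .spec_random_forest,
                 svm = .spec_svm, xgboost = .spec_xgboost)
  stats::setNames(lapply(families, function(f) makers[[f]]()), families)
}

# ---- resampling -------------------------------------------------------------

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lvl in levels(y)) {
    idx <- which(y == lvl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Generate stratified train/test splits
#'
#' Three resampling strategies: \code{"cv10x10"} (stratified 10-fold
#' cross-validation repeated \code{n_reps} times; default 10 repeats = 100
#' pairs), \code{"holdout82"} and \code{"holdout64"} (stratified random
#' 8:2 / 6:4 training-test splits, \code{n_reps} pairs; default 100).
#' Stratification keeps the class ratio in every test set (with 48 + 48
#' subjects each CV test fold holds 4-5 of each class).
#'
#' @param labels Factor (or character) of group labels.
#' @param strategy One of \code{"cv10x10"}, \code{"holdout82"},
#'   \code{"holdout64"}.
#' @param n_reps CV repeats or holdout repetitions; NULL = the strategy's
#'   default (10 repeats / 100 holdouts).
#' @param seed Optional integer seed.
#' @return List of \code{list(train, test)} index pairs, with the strategy
#'   stored in \code{attr(, "strategy")}.
#' @export
make_splits <- function(labels, strategy = c("cv10x10", "holdout82", "holdout64"),
                        n_reps = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  y <- factor(as.character(labels))
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  splits <- list()
  if (strategy == "cv10x10") {
    if (min(table(y)) < 10L) stop("10-fold CV needs at least 10 members per class")
    repeats <- if (is.null(n_reps)) 10L else n_reps
    for (r in seq_len(repeats)) {
      fold <- .stratified_folds(y, 10L)
      for (k in seq_len(10L))
        splits[[length(splits) + 1L]] <- list(train = which(fold != k),
                                              test = which(fold == k))
    }
  } else {
    p_test <- if (strategy == "holdout82") 0.2 else 0.4
    reps <- if (is.null(n_reps)) 100L else n_reps
    for (r in seq_len(reps)) {
      test <- unlist(lapply(levels(y), function(lvl) {
        idx <- which(y == lvl)
        sample(idx, round(p_test * length(idx)))
      }))
      splits[[length(splits) + 1L]] <- list(train = setdiff(seq_len(n), test),
                                            test = sort(test))
    }
  }
  attr(splits, "strategy") <- strategy
  splits
}

# ---- tuning and evaluation --------------------------------------------------

#' Grid-search hyperparameters by 5-fold cross-validation and refit
#'
#' Exhaustively evaluates the spec's grid by stratified \code{inner_folds}-
#' fold cross-validated accuracy on the training set, picks the best setting
#' (ties: the first grid row in documented order) and refits it on the full
#' training set.
#'
#' @param X Training predictors (data frame).
#' @param y Training labels (two-level factor).
#' @param spec A classifier spec from \code{\link{classifier_specs}}.
#' @param inner_folds Inner CV folds (default 5).
#' @param folds Optional precomputed fold assignment (testing hook).
#' @return List: \code{family}, \code{model}, \code{params} (chosen grid
#'   row), \code{cv_accuracy} (mean CV accuracy per grid row) and the spec.
#' @export
tune_and_fit <- function(X, y, spec, inner_folds = 5L, folds = NULL) {
  X <- as.data.frame(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("training set must contain both classes")
  if (is.null(folds)) folds <- .stratified_folds(y, inner_folds)
  k <- max(folds)
  accs <- matrix(NA_real_, k, nrow(spec$grid))
  for (i in seq_len(k)) {
    tr <- folds != i
    accs[i, ] <- spec$eval_fold(X[tr, , drop = FALSE], y[tr],
                                X[!tr, , drop = FALSE], y[!tr])
  }
  cv_acc <- colMeans(accs)
  best <- which.max(cv_acc)   # first maximum = first grid row in order
  params <- spec$grid[best, , drop = FALSE]
  list(family = spec$family, model = spec$fit(X, y, params), params = params,
       cv_accuracy = cv_acc, spec = spec)
}

#' Predict from a tuned fit
#' @param fitted Result of \code{\link{tune_and_fit}}.
#' @param X New data.
#' @return List with \code{class} and \code{score}.
#' @export
classify_predict <- function(fitted, X) fitted$spec$predict(fitted$model, X)

.classification_metrics <- function(pred, truth, score) {
  is_pos <- truth == .positive
  c(accuracy = mean(pred == truth),
    sensitivity = mean(pred[is_pos] == .positive),
    specificity = mean(pred[!is_pos] != .positive),
    auc = rank_auc(score, is_pos))
}

#' Evaluate one feature combination under one classifier and resampling
#'
#' For every train/test pair: tune and refit on the training set
#' (\code{\link{tune_and_fit}}), predict the test set, and compute accuracy,
#' sensitivity, specificity and AUC (AUC from the family's continuous score
#' -- class probability, vote fraction or decision value). The four indices
#' are averaged over all pairs.
#'
#' @param dataset Dataset matrix (\code{var_*} columns + \code{label}).
#' @param features Character vector of descriptor columns to use.
#' @param spec Classifier spec.
#' @param splits Train/test pairs from \code{\link{make_splits}}.
#' @return One-row data frame: combination size, mean indices, n_reps.
#' @export
evaluate_combination <- function(dataset, features, spec, splits) {
  stopifnot(all(features %in% names(dataset)))
  X <- dataset[features]
  y <- dataset$label
  per <- vapply(splits, function(sp) {
    fit <- tune_and_fit(X[sp$train, , drop = FALSE], y[sp$train], spec)
    pr <- classify_predict(fit, X[sp$test, , drop = FALSE])
    .classification_metrics(pr$class, y[sp$test], pr$score)
  }, numeric(4))
  data.frame(classifier = spec$family,
             accuracy = mean(per["accuracy", ]),
             sensitivity = mean(per["sensitivity", ]),
             specificity = mean(per["specificity", ]),
             auc = mean(per["auc", ]),
             n_reps = length(splits))
}

#' Run the full multi-classifier discriminability analysis
#'
#' Evaluates every (feature combination) x (classifier family) cell under
#' each resampling strategy. All randomness flows from \code{seed}: splits
#' are generated once per strategy (shared by all cells so classifiers are
#' compared on identical partitions), and each cell re-seeds its tuning RNG
#' from a deterministic offset of \code{seed}, so any single cell is
#' independently reproducible.
#'
#' @param dataset Dataset matrix.
#' @param combinations Named list of feature combinations (default: all 17).
#' @param families Classifier families (default: all six).
#' @param strategies Resampling strategies (default: all three).
#' @param seed Master integer seed.
#' @param cv_repeats,holdout_reps Repetition counts passed to
#'   \code{\link{make_splits}} (defaults 10 and 100, i.e. 100 test sets per
#'   strategy).
#' @param verbose Print progress.
#' @return Tidy data frame: one row per (combination, classifier, strategy)
#'   with the four mean indices and \code{n_reps}.
#' @export
run_classification <- function(dataset, combinations = feature_combinations(),
                               families = .classifier_families,
                               strategies = c("cv10x10", "holdout82", "holdout64"),
                               seed = 1L, cv_repeats = 10L, holdout_reps = 100L,
                               verbose = FALSE) {
  specs <- classifier_specs(families)
  out <- list()
  for (si in seq_along(strategies)) {
    strategy <- strategies[si]
    n_reps <- if (strategy == "cv10x10") cv_repeats else holdout_reps
    splits <- make_splits(dataset$label, strategy, n_reps = n_reps,
                          seed = seed + 7919L * si)
    for (ci in seq_along(combinations)) {
      for (fi in seq_along(specs)) {
        cell_seed <- (seed + 1000003 * si + 1009 * ci + fi) %% .Machine$integer.max
        set.seed(cell_seed)
        row <- evaluate_combination(dataset, combinations[[ci]], specs[[fi]], splits)
        row <- cbind(data.frame(combination = names(combinations)[ci],
                                strategy = strategy), row)
        out[[length(out) + 1L]] <- row
        if (verbose)
          message(sprintf("%s / %s / %s: accuracy %.3f", strategy,
                          names(combinations)[ci], row$classifier, row$accuracy))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average feature-combination ranks across classifiers
#'
#' Within each classifier and performance index the combinations are ranked
#' descending by mean index (best = 1, ties get the average rank); the ranks
#' are then averaged over the classifiers. Lower is better. Because
#' average-rank ties preserve the rank sum, each index column sums to
#' (C + 1) * C / 2 over the C combinations (153 for C = 17).
#'
#' @param results Rows of \code{\link{run_classification}} for a single
#'   resampling strategy.
#' @return Data frame: \code{combination} plus one averaged-rank column per
#'   index (\code{accuracy}, \code{sensitivity}, \code{specificity},
#'   \code{auc}).
#' @export
averaged_ranking <- function(results) {
  if (length(unique(results$strategy)) > 1L)
    stop("rankings are per strategy; subset the results first")
  indices <- c("accuracy", "sensitivity", "specificity", "auc")
  combos <- unique(results$combination)
  ranks <- vapply(indices, function(ix) {
    per_clf <- vapply(unique(results$classifier), function(cl) {
      sub <- results[results$classifier == cl, ]
      r <- rank(-sub[[ix]], ties.method = "average")
      r[match(combos, sub$combination)]
    }, numeric(length(combos)))
    rowMeans(matrix(per_clf, nrow = length(combos)))
  }, numeric(length(combos)))
  out <- data.frame(combination = combos, ranks)
  names(out) <- c("combination", indices)
  rownames(out) <- NULL
  out
}
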