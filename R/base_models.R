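# Base classifiers: gradient-boosted trees (xgboost) and an in-package
# brute-force k-NN store. The k-NN is deliberately a plain (X, y) store so a
# session's record can be inserted in O(1) and vote-fraction probabilities
# and per-class centroids stay exact under incremental retraining.

#' Boosted-tree model specification
#'
#' Multiclass softmax objective (probabilities exposed via the softprob
#' variant of the same model). The initial maximum depth is twice the number
#' of classes; tuning replaces it via grid search. Any of the recognised
#' hyperparameters (`booster`, `eta`/`learning_rate`, `n_estimators`,
#' `max_depth`, `min_child_weight`, `gamma`, `subsample`,
#' `colsample_bytree`, `reg_alpha`, `reg_lambda`) may be supplied in `grid`
#' as a vector; the search runs over the Cartesian product of all vector
#' entries. Defaults tune `eta` \{0.05, 0.1, 0.3\}, `n_estimators`
#' \{50, 100, 200\} and `max_depth` \{3, 2C, 4C\} (C = number of classes)
#' and hold the remaining parameters at fixed values.
#'
#' @param grid Named list of hyperparameter values (vectors allowed).
#'   `max_depth = NULL` expands to `c(3, 2C, 4C)` at training time.
#' @param warm_rounds Boosting rounds added per incremental update.
#' @param seed Integer seed for the booster's internal randomness.
#' @return An object of class `boosted_spec`.
#' @export
boosted_spec <- function(grid = list(), warm_rounds = 5, seed = 1L) {
  if (!is.null(grid$learning_rate)) { # alias
    grid$eta <- grid$learning_rate
    grid$learning_rate <- NULL
  }
  defaults <- list(booster = "gbtree", eta = c(0.05, 0.1, 0.3),
                   n_estimators = c(50, 100, 200), max_depth = NULL,
                   min_child_weight = 1, gamma = 0, subsample = 1,
                   colsample_bytree = 1, reg_alpha = 0, reg_lambda = 1)
  unknown <- setdiff(names(grid), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown boosted hyperparameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  spec <- utils::modifyList(defaults, grid, keep.null = TRUE)
  structure(list(objective = "multi:softprob", grid = spec,
                 warm_rounds = as.integer(warm_rounds),
                 seed = as.integer(seed)),
            class = "boosted_spec")
}

#' k-NN model specification
#'
#' Euclidean distance on the normalized features; class probabilities are
#' neighbour vote fractions. `k = 5` is the pre-tuning default; grid search
#' selects `k` from `k_grid` (capped at the fold training size).
#'
#' @param k Initial neighbour count.
#' @param k_grid Candidate values of `k` for tuning.
#' @return An object of class `knn_spec`.
#' @export
knn_spec <- function(k = 5, k_grid = c(1, 3, 5, 7, 9)) {
  stopifnot(k >= 1, all(k_grid >= 1))
  structure(list(k = as.integer(k), k_grid = as.integer(k_grid)),
            class = "knn_spec")
}

# expand a spec grid into a data.frame of configurations, resolving the
# depth placeholder against the class count
expand_boosted_grid <- function(spec, n_classes) {
  g <- spec$grid
  if (is.null(g$max_depth)) {
    g$max_depth <- unique(c(3, 2 * n_classes, 4 * n_classes))
  }
  g$booster <- as.character(g$booster)
  expand.grid(g, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

xgb_params <- function(config, n_classes, seed) {
  list(objective = "multi:softprob", num_class = n_classes,
       booster = config$booster, eta = config$eta,
       max_depth = config$max_depth,
       min_child_weight = config$min_child_weight, gamma = config$gamma,
       subsample = config$subsample,
       colsample_bytree = config$colsample_bytree,
       alpha = config$reg_alpha, lambda = config$reg_lambda,
       base_score = 0.5, nthread = 1, seed = as.integer(seed))
}

train_xgb <- function(X, y, config, n_classes, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = xgb_params(config, n_classes, seed),
                     data = dtrain, nrounds = config$n_estimators,
                     verbose = 0)
}

row_softmax <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Incremental boosted model: a chain of boosters whose class margins add up.
# The first member is the tuned base model; each incremental update appends a
# small booster trained on top of the cached margins of the accumulated
# training set, so the per-update training cost does not grow with the number
# of past updates (additive boosting continuation, identical to a warm start
# up to a constant that cancels in the softmax).

# margin prediction for one chain member, returned as an n x n_classes
# matrix. Long chains make the R-level predict() dispatch the bottleneck of a
# session, so the booster's C predictor is called directly; any failure falls
# back to the public interface.
.xgb_margin_config <- paste0('{"type":1,"training":false,"iteration_begin":0,',
                             '"iteration_end":0,"strict_shape":false}')
xgb_member_margin <- function(b, dm, n_rows, n_classes) {
  m <- tryCatch(
    .Call(xgboost:::XGBoosterPredictFromDMatrix_R,
          xgboost:::xgb.get.handle(b), dm, .xgb_margin_config),
    error = function(e) NULL)
  if (is.null(m)) {
    return(matrix(predict(b, dm, outputmargin = TRUE), nrow = n_rows,
                  ncol = n_classes))
  }
  # the C predictor returns class-major values
  t(matrix(m, nrow = n_classes, ncol = n_rows))
}

xgb_chain_margin <- function(chain, X, n_classes) {
  dm <- xgboost::xgb.DMatrix(X, nthread = 1)
  out <- matrix(0, nrow = nrow(X), ncol = n_classes)
  for (b in chain) {
    out <- out + xgb_member_margin(b, dm, nrow(X), n_classes)
  }
  out
}

predict_xgb_probs <- function(chain, X, n_classes) {
  row_softmax(xgb_chain_margin(chain, X, n_classes))
}

# brute-force k-NN vote fractions; deterministic distance ties (by index)
predict_knn_probs <- function(store, X, n_classes) {
  k <- min(store$k, nrow(store$X))
  out <- matrix(0, nrow = nrow(X), ncol = n_classes)
  for (i in seq_len(nrow(X))) {
    d <- sqrt(colSums((t(store$X) - X[i, ])^2))
    nn <- order(d)[seq_len(k)]
    votes <- tabulate(store$y[nn] + 1L, nbins = n_classes)
    out[i, ] <- votes / k
  }
  out
}

# stratified fold assignment; errors when a class cannot reach every fold
stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < folds) {
        stop("class code ", cls, " has fewer than ", folds,
             " training records; stratified folding impossible",
             call. = FALSE)
      }
      assign[idx] <- rep_len(seq_len(folds), length(idx))[sample.int(length(idx))]
    }
  })
  assign
}

#' Tune and train the boosted-tree / k-NN model pair
#'
#' The central fitting function. Performs a seeded stratified 80/20
#' train/test split, fits the \eqn{[-1, 1]} normalizer on the training split
#' only, then selects each base model's hyperparameters by stratified
#' k-fold cross-validated grid search (mean fold accuracy; ties resolved by
#' grid order). Both models are refit on the full training split. The fitted
#' pair carries the normalizer, per-class centroids in normalized feature
#' space (the reference points for the hybrid engine's distance rule),
#' xgboost gain-based feature importances, and the held-out test split.
#'
#' @param dataset A labelled, unnormalized [rehab_dataset()].
#' @param axis `"difficulty"` or `"condition"`.
#' @param boosted A [boosted_spec()].
#' @param knn A [knn_spec()].
#' @param folds Cross-validation folds (default 5).
#' @param split Training fraction (default 0.8).
#' @param seed Integer seed governing split, folds and boosters.
#' @return An object of class `model_pair`; its `cv_report` element holds
#'   per-configuration mean and per-fold accuracies and the chosen
#'   hyperparameters.
#' @seealso [predict.model_pair()], [incremental_update()], [class_centroids()]
#' @export
rehab_train <- function(dataset, axis = c("difficulty", "condition"),
                        boosted = boosted_spec(), knn = knn_spec(),
                        folds = 5, split = 0.8, seed) {
  stopifnot(inherits(dataset, "rehab_dataset"),
            inherits(boosted, "boosted_spec"), inherits(knn, "knn_spec"))
  axis <- match.arg(axis)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!is.null(dataset$normalization)) {
    stop("rehab_train expects raw (unnormalized) data; it fits its own ",
         "normalizer on the training split", call. = FALSE)
  }
  if (!axis %in% names(dataset$data)) {
    stop("dataset has no '", axis, "' labels", call. = FALSE)
  }
  tax <- dataset$taxonomies[[axis]]
  feats <- rehab_features()
  df <- dataset$data
  y_all <- label_code(df[[axis]], tax)
  n_classes <- length(tax$classes)

  # stratified train/test split
  test_idx <- integer(0)
  with_seed(derive_seed(seed, 1), {
    for (cls in unique(y_all)) {
      idx <- which(y_all == cls)
      n_test <- round((1 - split) * length(idx))
      if (n_test > 0) {
        test_idx <- c(test_idx, idx[sample.int(length(idx), n_test)])
      }
    }
  })
  train_idx <- setdiff(seq_len(nrow(df)), test_idx)

  train_ds <- dataset
  train_ds$data <- df[train_idx, , drop = FALSE]
  norm <- fit_normalizer(train_ds)
  X_train <- normalize_values(df[train_idx, ], norm)
  y_train <- y_all[train_idx]

  fold_of <- stratified_folds(y_train, folds, derive_seed(seed, 2))

  # ---- xgboost grid search ----
  grid <- expand_boosted_grid(boosted, n_classes)
  xgb_fold_acc <- matrix(NA_real_, nrow = nrow(grid), ncol = folds)
  for (f in seq_len(folds)) {
    in_f <- fold_of == f
    d_fit <- xgboost::xgb.DMatrix(X_train[!in_f, , drop = FALSE],
                                  label = y_train[!in_f], nthread = 1)
    d_val <- xgboost::xgb.DMatrix(X_train[in_f, , drop = FALSE], nthread = 1)
    for (g in seq_len(nrow(grid))) {
      bst <- xgboost::xgb.train(
        params = xgb_params(grid[g, ], n_classes, boosted$seed),
        data = d_fit, nrounds = grid$n_estimators[g], verbose = 0)
      p <- matrix(predict(bst, d_val), ncol = n_classes)
      pred <- max.col(p, ties.method = "first") - 1L
      xgb_fold_acc[g, f] <- mean(pred == y_train[in_f])
    }
  }
  xgb_mean_acc <- rowMeans(xgb_fold_acc)
  best_g <- which.max(xgb_mean_acc)

  # ---- k-NN grid search (same folds) ----
  k_grid <- unique(pmin(knn$k_grid, min(tabulate(fold_of)) *
                          (folds - 1))) # never exceed fold-train size
  knn_fold_acc <- matrix(NA_real_, nrow = length(k_grid), ncol = folds)
  for (f in seq_len(folds)) {
    in_f <- fold_of == f
    store_X <- X_train[!in_f, , drop = FALSE]
    store_y <- y_train[!in_f]
    for (ki in seq_along(k_grid)) {
      store <- list(X = store_X, y = store_y, k = k_grid[ki])
      p <- predict_knn_probs(store, X_train[in_f, , drop = FALSE], n_classes)
      pred <- max.col(p, ties.method = "first") - 1L
      knn_fold_acc[ki, f] <- mean(pred == y_train[in_f])
    }
  }
  knn_mean_acc <- rowMeans(knn_fold_acc)
  best_k <- k_grid[which.max(knn_mean_acc)]

  # ---- refit on the full training split ----
  booster <- train_xgb(X_train, y_train, grid[best_g, ], n_classes,
                       boosted$seed)
  xgb_margin <- matrix(
    predict(booster, xgboost::xgb.DMatrix(X_train, nthread = 1),
            outputmargin = TRUE), ncol = n_classes)

  imp <- rep(0, length(feats))
  names(imp) <- feats
  imp_tab <- tryCatch(xgboost::xgb.importance(model = booster),
                      error = function(e) NULL)
  if (!is.null(imp_tab) && nrow(imp_tab) > 0) {
    imp[imp_tab$Feature] <- imp_tab$Gain
  }
  imp <- if (sum(imp) > 0) imp / sum(imp) else
    stats::setNames(rep(1 / length(feats), length(feats)), feats)

  centroids <- matrix(NA_real_, nrow = n_classes, ncol = length(feats),
                      dimnames = list(tax$classes, feats))
  counts <- stats::setNames(integer(n_classes), tax$classes)
  for (cls in unique(y_train)) {
    rows <- X_train[y_train == cls, , drop = FALSE]
    centroids[cls + 1L, ] <- colMeans(rows)
    counts[cls + 1L] <- nrow(rows)
  }

  cv_report <- list(
    xgb = cbind(grid, mean_accuracy = xgb_mean_acc, xgb_fold_acc),
    knn = data.frame(k = k_grid, mean_accuracy = knn_mean_acc),
    chosen = list(xgb = as.list(grid[best_g, ]), knn_k = best_k),
    folds = folds, split = split, seed = seed)

  structure(
    list(axis = axis, taxonomy = tax, features = feats,
         normalizer = norm, xgb_chain = list(booster),
         xgb_margin = xgb_margin,
         xgb_config = grid[best_g, ], warm_rounds = boosted$warm_rounds,
         xgb_seed = boosted$seed, n_classes = n_classes,
         knn = list(X = X_train, y = y_train, k = best_k),
         centroids = centroids, class_counts = counts,
         feature_importances = imp, cv_report = cv_report,
         test = list(data = df[test_idx, , drop = FALSE],
                     y = y_all[test_idx], idx = test_idx),
         update_log = character(0)),
    class = "model_pair")
}

#' @export
print.model_pair <- function(x, ...) {
  cat(sprintf("<model_pair> %s %s (%d classes)\n", x$taxonomy$test_type,
              x$axis, x$n_classes))
  cat(sprintf("  xgboost: eta=%g, n_estimators=%d, max_depth=%d (CV acc %.3f)\n",
              x$xgb_config$eta, x$xgb_config$n_estimators,
              x$xgb_config$max_depth,
              max(x$cv_report$xgb$mean_accuracy)))
  cat(sprintf("  k-NN: k=%d (CV acc %.3f), store %d records\n", x$knn$k,
              max(x$cv_report$knn$mean_accuracy), nrow(x$knn$X)))
  cat(sprintf("  incremental updates applied: %d (booster chain length %d)\n",
              length(x$update_log), length(x$xgb_chain)))
  invisible(x)
}

#' @export
summary.model_pair <- function(object, ...) {
  print(object)
  cat("feature importances (gain, sum 1):\n")
  print(round(object$feature_importances, 4))
  cat("class centroid coverage:",
      sum(object$class_counts > 0), "of", object$n_classes, "classes\n")
  invisible(object)
}

#' Predict classes and probabilities from both base models
#'
#' @param object A fitted `model_pair`.
#' @param newdata Data frame (or named vector for one record) of raw feature
#'   values; normalized internally with the pair's fitted parameters.
#' @param ... Unused.
#' @return List with elements `xgb` and `knn`, each holding `class`
#'   (character), `code` (0-based integer) and `prob` (rows summing to 1;
#'   argmax ties resolved toward the lowest class code).
#' @export
predict.model_pair <- function(object, newdata, ...) {
  if (is.null(object$normalizer)) {
    stop("model pair has no fitted normalization parameters", call. = FALSE)
  }
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  X <- normalize_values(newdata, object$normalizer)
  n_classes <- object$n_classes
  p_x <- predict_xgb_probs(object$xgb_chain, X, n_classes)
  p_k <- predict_knn_probs(object$knn, X, n_classes)
  to_out <- function(p) {
    code <- max.col(p, ties.method = "first") - 1L
    list(class = label_name(code, object$taxonomy), code = code,
         prob = `colnames<-`(p, object$taxonomy$classes))
  }
  list(xgb = to_out(p_x), knn = to_out(p_k))
}

#' Predict a single record with per-model probability vectors
#'
#' Convenience wrapper over [predict.model_pair()] for one subject record,
#' the form the hybrid engine consumes.
#'
#' @param pair A fitted `model_pair`.
#' @param record Named numeric vector or 1-row data frame of raw features.
#' @return As [predict.model_pair()], with `prob` a named vector per model.
#' @export
predict_with_probs <- function(pair, record) {
  out <- predict(pair, record)
  for (m in names(out)) {
    out[[m]]$class <- out[[m]]$class[1]
    out[[m]]$code <- out[[m]]$code[1]
    out[[m]]$prob <- out[[m]]$prob[1, ]
  }
  out
}

#' Per-class centroids of a normalized dataset
#'
#' The centroid of a class is the arithmetic mean of its records' normalized
#' feature vectors (labels excluded). These are the reference points for the
#' hybrid engine's distance-to-healthy rule.
#'
#' @param dataset A normalized, labelled [rehab_dataset()].
#' @param axis Label axis.
#' @return Matrix (classes present x features).
#' @export
class_centroids <- function(dataset, axis = c("difficulty", "condition")) {
  stopifnot(inherits(dataset, "rehab_dataset"))
  axis <- match.arg(axis)
  if (is.null(dataset$normalization)) {
    stop("centroids are defined in normalized feature space", call. = FALSE)
  }
  labs <- dataset$data[[axis]]
  feats <- rehab_features()
  classes <- unique(labs)
  out <- matrix(NA_real_, nrow = length(classes), ncol = length(feats),
                dimnames = list(classes, feats))
  for (cls in classes) {
    rows <- dataset$data[labs == cls, feats, drop = FALSE]
    if (nrow(rows) == 0) stop("empty class '", cls, "'", call. = FALSE)
    out[cls, ] <- colMeans(rows)
  }
  out
}

#' Incrementally update a model pair with one labelled record
#'
#' The k-NN store gains the (normalized) record — an O(1) insertion whose
#' cost does not grow with history. The labelled class's centroid is updated
#' as a running mean. The boosted model is warm-started: `warm_rounds`
#' additional boosting rounds are fitted on the accumulated training set
#' including the new point, on top of the cached class margins of the
#' existing ensemble — no existing tree is discarded or re-evaluated, so the
#' training cost of an update does not grow with the number of past updates.
#'
#' @param pair A fitted `model_pair`.
#' @param record Named numeric vector or 1-row data frame of raw features.
#' @param label Class name within the pair's taxonomy.
#' @return The updated `model_pair`.
#' @export
incremental_update <- function(pair, record, label) {
  stopifnot(inherits(pair, "model_pair"))
  code <- label_code(label, pair$taxonomy) # errors on unknown label
  if (!is.data.frame(record)) record <- as.data.frame(as.list(record))
  x <- normalize_values(record, pair$normalizer)[1, ]

  new_margin <- xgb_chain_margin(pair$xgb_chain,
                                 matrix(x, nrow = 1,
                                        dimnames = list(NULL, names(x))),
                                 pair$n_classes)

  pair$knn$X <- rbind(pair$knn$X, x, deparse.level = 0)
  pair$knn$y <- c(pair$knn$y, code)

  cnt <- pair$class_counts[[label]]
  pair$centroids[label, ] <- if (cnt == 0) x else
    (pair$centroids[label, ] * cnt + x) / (cnt + 1)
  pair$class_counts[[label]] <- cnt + 1L

  pair$xgb_margin <- rbind(pair$xgb_margin, new_margin)
  dtrain <- xgboost::xgb.DMatrix(pair$knn$X, label = pair$knn$y, nthread = 1)
  xgboost::setinfo(dtrain, "base_margin", pair$xgb_margin)
  member <- xgboost::xgb.train(
    params = xgb_params(pair$xgb_config, pair$n_classes, pair$xgb_seed),
    data = dtrain, nrounds = pair$warm_rounds, verbose = 0)
  pair$xgb_margin <- pair$xgb_margin +
    xgb_member_margin(member, xgboost::xgb.DMatrix(pair$knn$X, nthread = 1),
                      nrow(pair$knn$X), pair$n_classes)
  pair$xgb_chain <- c(pair$xgb_chain, list(member))
  pair$update_log <- c(pair$update_log, label)
  pair
}

#' Test-split accuracy of a model pair
#'
#' Accuracy of each base model on the held-out 20% split stored at training
#' time.
#'
#' @param pair A fitted `model_pair`.
#' @return Named numeric vector `c(xgb = ..., knn = ...)`.
#' @export
test_accuracy <- function(pair) {
  stopifnot(inherits(pair, "model_pair"))
  if (nrow(pair$test$data) == 0) stop("pair holds no test split", call. = FALSE)
  pred <- predict(pair, pair$test$data)
  c(xgb = mean(pred$xgb$code == pair$test$y),
    knn = mean(pred$knn$code == pair$test$y))
}
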