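# Parameter-importance ranking for the dose-coefficient response: random
# forest surrogate with impurity-based importances, exact tree-path Shapley
# attributions, and held-out error metrics.

#' Min-max scale a response vector
#'
#' @param y numeric vector with at least two distinct values.
#' @return a `scaled_response`: list with `values` in \[0, 1\] and the
#'   stored original `min`/`max` for inversion.
#' @export
minmax_scale <- function(y) {
  if (length(y) < 2L || min(y) == max(y)) {
    stop("min-max scaling undefined for a constant response")
  }
  structure(list(values = (y - min(y)) / (max(y) - min(y)),
                 min = min(y), max = max(y)), class = "scaled_response")
}

#' Invert a min-max scaled response
#' @param scaled a `scaled_response`.
#' @param values scaled values to invert (default: the stored ones).
#' @return values on the original scale.
#' @export
minmax_unscale <- function(scaled, values = scaled$values) {
  values * (scaled$max - scaled$min) + scaled$min
}

#' Random-forest surrogate configuration
#'
#' @param tree_grid tree counts searched over (test-set RMSE decides; ties
#'   go to fewer trees).
#' @param test_fraction held-out fraction in (0, 1); default 0.25.
#' @param nodesize minimum terminal-node size; the default 1 grows nodes
#'   until leaves are pure.
#' @param seed seed controlling the split and the forest randomness.
#' @return an `ensemble_config` list.
#' @export
ensemble_config <- function(tree_grid = c(50, 100, 150, 200, 300),
                            test_fraction = 0.25, nodesize = 1, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)")
  }
  if (any(tree_grid < 1)) stop("tree counts must be >= 1")
  structure(list(tree_grid = sort(unique(as.integer(tree_grid))),
                 test_fraction = test_fraction,
                 nodesize = as.integer(nodesize), seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Mean absolute and root-mean-square error
#'
#' @param y_true,y_pred equal-length non-empty numeric vectors.
#' @return list with `mae` and `rmse`; RMSE >= MAE always.
#' @export
error_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0L) {
    stop("y_true and y_pred must be non-empty and of equal length")
  }
  d <- y_true - y_pred
  list(mae = mean(abs(d)), rmse = sqrt(mean(d ^ 2)))
}

#' Fit the random-forest surrogate with a tree-count grid search
#'
#' The data are split into a seeded 75/25 train/test partition, a random
#' forest is fitted for each candidate tree count, the count with the
#' smallest test RMSE is selected (ties resolved towards fewer trees), and
#' the selected forest is refitted as the final model. MAE/RMSE on both
#' partitions are reported.
#'
#' @param X feature matrix (rows = samples, named columns).
#' @param y response: a `scaled_response` or numeric vector.
#' @param config an [ensemble_config()].
#' @return a `sensitivity_model`: list with the fitted `forest`, selected
#'   `ntree`, `metrics` (train/test MAE+RMSE), the `grid` search table,
#'   split indices and feature names.
#' @export
fit_ensemble <- function(X, y, config = ensemble_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have named columns")
  yv <- if (inherits(y, "scaled_response")) y$values else as.numeric(y)
  n <- nrow(X)
  if (n < 40L) stop("need at least 40 samples to fit the surrogate")
  if (length(yv) != n) stop("X and y sizes differ")
  keep <- apply(X, 2, function(col) length(unique(col)) > 1L)
  if (!any(keep)) stop("degenerate feature matrix: all columns constant")

  n_test <- max(1L, round(config$test_fraction * n))
  test_idx <- with_seed(config$seed, sample.int(n, n_test))
  train_idx <- setdiff(seq_len(n), test_idx)

  fit_one <- function(ntree) {
    with_seed(config$seed + ntree, {
      randomForest::randomForest(
        x = X[train_idx, , drop = FALSE], y = yv[train_idx],
        ntree = ntree, nodesize = config$nodesize, importance = FALSE
      )
    })
  }
  grid <- data.frame(ntree = config$tree_grid, test_rmse = NA_real_)
  for (i in seq_len(nrow(grid))) {
    m <- fit_one(grid$ntree[i])
    pred <- predict(m, X[test_idx, , drop = FALSE])
    grid$test_rmse[i] <- error_metrics(yv[test_idx], pred)$rmse
  }
  best <- grid$ntree[which.min(grid$test_rmse)] # ties: first = fewest trees
  forest <- fit_one(best)

  metrics <- list(
    train = error_metrics(yv[train_idx],
                          predict(forest, X[train_idx, , drop = FALSE])),
    test = error_metrics(yv[test_idx],
                         predict(forest, X[test_idx, , drop = FALSE]))
  )
  structure(list(forest = forest, ntree = best, metrics = metrics,
                 grid = grid, train_idx = train_idx, test_idx = test_idx,
                 X_train = X[train_idx, , drop = FALSE],
                 feature_names = colnames(X), config = config),
            class = "sensitivity_model")
}

#' @export
print.sensitivity_model <- function(x, ...) {
  cat("<random-forest sensitivity surrogate> ntree =", x$ntree, "\n")
  cat(sprintf("  train MAE %.4f RMSE %.4f | test MAE %.4f RMSE %.4f\n",
              x$metrics$train$mae, x$metrics$train$rmse,
              x$metrics$test$mae, x$metrics$test$rmse))
  invisible(x)
}

#' Impurity-based feature importances
#'
#' The total decrease in node impurity (residual sum of squares) from
#' splits on each feature, summed over all trees and normalised to one.
#'
#' @param model a `sensitivity_model`.
#' @return named numeric vector, non-negative, summing to one.
#' @export
impurity_importance <- function(model) {
  if (!inherits(model, "sensitivity_model")) {
    stop("model must be a fitted sensitivity_model")
  }
  imp <- randomForest::importance(model$forest, type = 2)[, 1]
  imp <- pmax(imp, 0)
  imp / sum(imp)
}

# getTree output -> 0-based arrays for the C++ kernels
flatten_tree <- function(forest, k) {
  tr <- randomForest::getTree(forest, k, labelVar = FALSE)
  leaf <- tr[, "status"] == -1
  list(
    left = as.integer(ifelse(leaf, -1L, tr[, "left daughter"] - 1L)),
    right = as.integer(ifelse(leaf, -1L, tr[, "right daughter"] - 1L)),
    feature = as.integer(ifelse(leaf, -1L, tr[, "split var"] - 1L)),
    threshold = as.numeric(tr[, "split point"]),
    value = as.numeric(tr[, "prediction"])
  )
}

#' Exact per-sample Shapley attributions for the surrogate
#'
#' Computes exact tree-path Shapley attributions for every row of `X`,
#' averaged over the forest, using the training partition as the
#' reference measure (node covers). The attributions satisfy local
#' accuracy: base value + row sum equals the forest prediction.
#'
#' @param model a `sensitivity_model`.
#' @param X feature matrix with exactly the training columns.
#' @return an `attribution_matrix`: list with matrix `phi`
#'   (rows x features), scalar `base`, and the model `prediction` per row.
#' @export
shapley_attributions <- function(model, X) {
  if (!inherits(model, "sensitivity_model")) {
    stop("model must be a fitted sensitivity_model")
  }
  X <- as.matrix(X)
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature names of X do not match the training features")
  }
  ntree <- model$forest$ntree
  phi <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  base <- 0
  for (k in seq_len(ntree)) {
    tr <- flatten_tree(model$forest, k)
    cover <- tree_node_counts_cpp(tr$left, tr$right, tr$feature,
                                  tr$threshold, model$X_train)
    phi <- phi + tree_shap_cpp(tr$left, tr$right, tr$feature, tr$threshold,
                               tr$value, cover, X)
    base <- base + tree_expected_value_cpp(tr$left, tr$value, cover)
  }
  phi <- phi / ntree
  base <- base / ntree
  structure(list(phi = phi, base = base,
                 prediction = base + rowSums(phi)),
            class = "attribution_matrix")
}

#' Full importance report
#'
#' Combines the impurity importances and the mean absolute Shapley
#' attribution per feature into one ranking table.
#'
#' @param model a `sensitivity_model`.
#' @param X feature matrix to attribute (e.g. the design matrix or its
#'   test partition).
#' @return an `importance_report`: data frame with `feature`,
#'   `impurity_importance`, `mean_abs_shap`, ordered by impurity
#'   importance; the attribution matrix rides along as an attribute.
#' @export
importance_report <- function(model, X) {
  imp <- impurity_importance(model)
  attr_m <- shapley_attributions(model, X)
  mas <- colMeans(abs(attr_m$phi))
  tab <- data.frame(feature = names(imp),
                    impurity_importance = unname(imp),
                    mean_abs_shap = unname(mas[names(imp)]),
                    row.names = NULL)
  tab <- tab[order(-tab$impurity_importance), ]
  rownames(tab) <- NULL
  attr(tab, "attributions") <- attr_m
  class(tab) <- c("importance_report", "data.frame")
  tab
}

#' @export
print.importance_report <- function(x, n = 6, ...) {
  cat("<feature importance report>\n")
  print.data.frame(head(transform(x,
    impurity_importance = signif(impurity_importance, 3),
    mean_abs_shap = signif(mean_abs_shap, 3)), n))
  invisible(x)
}
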