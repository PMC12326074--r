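# Gradient-boosted regression trees (squared-error loss).
#
# Plain gradient boosting: stagewise fits of shallow CART regression trees
# to the current residuals, shrunk by a learning rate, with optional row
# subsampling (stochastic gradient boosting) and per-tree feature
# subsampling. Squared-error gradients make each stage a direct residual
# fit. No installed package provides this learner, so the trees live in
# src/tree.cpp and the boosting loop here.

#' Boosted-tree hyperparameters
#'
#' @param n_trees number of boosting stages.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param learning_rate shrinkage applied to every stage.
#' @param subsample fraction of rows sampled (without replacement) per tree;
#'   1 disables subsampling.
#' @param colsample fraction of features available to each tree.
#' @param min_leaf minimum observations per leaf.
#' @return a `tree_params` list.
#' @export
tree_params <- function(n_trees = 200L, max_depth = 3L, learning_rate = 0.05,
                        subsample = 1.0, colsample = 1.0, min_leaf = 5L) {
  stopifnot(n_trees >= 1L, max_depth >= 1L, learning_rate > 0,
            subsample > 0, subsample <= 1, colsample > 0, colsample <= 1,
            min_leaf >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, subsample = subsample,
                 colsample = colsample, min_leaf = as.integer(min_leaf)),
            class = "tree_params")
}

#' Fit a gradient-boosted regression-tree ensemble
#'
#' @param X numeric feature matrix (rows = observations).
#' @param y numeric response vector.
#' @param params a [tree_params()] configuration.
#' @param seed integer seed controlling row/feature subsampling.
#' @return a `gbdt` model.
#' @export
gbdt_fit <- function(X, y, params = tree_params(), seed = 0L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("X and y must be finite")
  }
  n <- nrow(X); p <- ncol(X)
  set.seed(as.integer(seed))
  f0 <- mean(y)
  n_sub <- max(2L, as.integer(round(params$subsample * n)))
  p_sub <- max(1L, as.integer(round(params$colsample * p)))
  row_samples <- vector("list", params$n_trees)
  col_samples <- vector("list", params$n_trees)
  for (m in seq_len(params$n_trees)) {
    row_samples[[m]] <- if (n_sub < n) sort(sample.int(n, n_sub)) - 1L
                        else seq_len(n) - 1L
    col_samples[[m]] <- if (p_sub < p) sort(sample.int(p, p_sub)) - 1L
                        else seq_len(p) - 1L
  }
  trees <- .gbdt_boost_cpp(X, y, row_samples, col_samples, params$max_depth,
                           params$min_leaf, params$learning_rate, f0)
  structure(list(f0 = f0, trees = trees, params = params,
                 n_features = p, seed = as.integer(seed)),
            class = "gbdt")
}

#' @rdname gbdt_fit
#' @param object a fitted `gbdt` model.
#' @param newdata numeric matrix with `n_features` columns.
#' @param ... unused.
#' @return `predict`: numeric vector of predictions.
#' @export
predict.gbdt <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric(0))
  if (ncol(newdata) != object$n_features) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(newdata), object$n_features))
  }
  out <- rep(object$f0, nrow(newdata))
  lr <- object$params$learning_rate
  for (tr in object$trees) {
    out <- out + lr * .predict_tree_cpp(tr, newdata)
  }
  out
}
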