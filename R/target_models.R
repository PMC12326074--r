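# Per-target boosted-tree models with seed-averaged, five-fold
# cross-validated metrics.
#
# For each of five random seeds: draw a fresh five-fold partition, gather
# out-of-fold predictions over all folds, compute Pearson R and RMSE on the
# pooled out-of-fold vector, then refit on the full dataset. The reported
# metrics are the arithmetic means over seeds; prediction averages the five
# full-data members.

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (>= 2), each with non-zero
#'   variance. Zero variance is an error, never a silent 0.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: an input has zero variance")
  }
  stats::cor(x, y)
}

#' Root-mean-square error
#'
#' @param pred,obs numeric vectors of equal length (>= 1).
#' @return non-negative RMSE.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (length(pred) < 1) stop("need at least 1 observation")
  sqrt(mean((pred - obs)^2))
}

#' Deterministic five-fold partition
#'
#' @param n number of observations (>= 5).
#' @param seed integer seed.
#' @return list of 5 disjoint integer index vectors covering `1:n`, sizes
#'   differing by at most 1.
#' @export
five_fold_split <- function(n, seed) {
  if (n < 5) stop("need n >= 5 for five folds")
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  fold_of <- rep(1:5, length.out = n)
  lapply(1:5, function(f) sort(idx[fold_of == f]))
}

#' Train a per-target boosted-tree ensemble with cross-validated metrics
#'
#' @param X numeric fingerprint matrix (rows = compounds).
#' @param y numeric binding-affinity labels (kcal/mol).
#' @param target_id target identifier.
#' @param seeds five distinct integer seeds (default 0:4).
#' @param params a [tree_params()] configuration.
#' @param min_train minimum training-set size (inclusive, default 100 to
#'   match the dataset-inclusion threshold).
#' @return list with `model` (a `target_model`: five full-data members plus
#'   seed-averaged `cv_pearson_r` / `cv_rmse`) and `cv` (a `cv_report` with
#'   per-seed pooled out-of-fold metrics).
#' @export
train_target_model <- function(X, y, target_id, seeds = 0:4,
                               params = tree_params(), min_train = 100L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (nrow(X) < min_train) {
    stop(sprintf("target '%s': %d training points < inclusion threshold %d",
                 target_id, nrow(X), min_train))
  }
  if (length(seeds) != 5 || anyDuplicated(seeds)) {
    stop("seeds must be 5 distinct integers")
  }
  if (stats::sd(y) == 0) stop("constant y: cross-validated R is undefined")
  n <- nrow(X)
  per_seed <- vector("list", length(seeds))
  members <- vector("list", length(seeds))
  for (si in seq_along(seeds)) {
    sd_i <- as.integer(seeds[si])
    folds <- five_fold_split(n, sd_i)
    oof <- numeric(n)
    fold_r <- numeric(5)
    fold_rmse <- numeric(5)
    for (f in 1:5) {
      test <- folds[[f]]
      train <- setdiff(seq_len(n), test)
      fit <- gbdt_fit(X[train, , drop = FALSE], y[train], params, seed = sd_i)
      oof[test] <- predict(fit, X[test, , drop = FALSE])
      fold_rmse[f] <- rmse(oof[test], y[test])
      fold_r[f] <- if (length(test) >= 2 && stats::sd(y[test]) > 0 &&
                       stats::sd(oof[test]) > 0) {
        pearson_r(oof[test], y[test])
      } else NA_real_
    }
    per_seed[[si]] <- list(seed = sd_i, fold_r = fold_r,
                           fold_rmse = fold_rmse,
                           pooled_r = pearson_r(oof, y),
                           pooled_rmse = rmse(oof, y))
    members[[si]] <- gbdt_fit(X, y, params, seed = sd_i)
  }
  mean_r <- mean(vapply(per_seed, `[[`, numeric(1), "pooled_r"))
  mean_rmse <- mean(vapply(per_seed, `[[`, numeric(1), "pooled_rmse"))
  model <- structure(list(target_id = target_id, members = members,
                          seeds = as.integer(seeds),
                          cv_pearson_r = mean_r, cv_rmse = mean_rmse,
                          n_train = n, params = params),
                     class = "target_model")
  cv <- structure(list(target_id = target_id, per_seed = per_seed,
                       mean_r = mean_r, mean_rmse = mean_rmse),
                  class = "cv_report")
  list(model = model, cv = cv)
}

#' @export
print.target_model <- function(x, ...) {
  cat(sprintf("target model '%s': %d seeded members, n=%d, CV R=%.3f, RMSE=%.3f kcal/mol\n",
              x$target_id, length(x$members), x$n_train, x$cv_pearson_r,
              x$cv_rmse))
  invisible(x)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv report '%s': mean R=%.3f, mean RMSE=%.3f over %d seeds\n",
              x$target_id, x$mean_r, x$mean_rmse, length(x$per_seed)))
  invisible(x)
}

#' Predict binding affinities with a target model
#'
#' Averages the predictions of the five seeded full-data members.
#'
#' @param model a `target_model`.
#' @param X fingerprint matrix with the training feature dimension.
#' @return numeric vector of predicted binding affinities (kcal/mol).
#' @export
predict_ba <- function(model, X) {
  stopifnot(inherits(model, "target_model"))
  X <- as.matrix(X)
  if (nrow(X) == 0) return(numeric(0))
  preds <- vapply(model$members, function(m) predict(m, X),
                  numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}
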