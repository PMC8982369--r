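# Gradient-boosted regression trees with squared-error loss, early stopping on
# training RMSE, percentage-scale feature importance, and grid-search tuning.

#' GBM configuration
#'
#' @param ntree maximum number of trees M.
#' @param learning_rate shrinkage weight applied to every tree (0, 1].
#' @param max_depth maximum tree depth (a stump has depth 1).
#' @param min_leaf minimum training samples per leaf (default 5).
#' @param stopping_rounds consecutive trees without a training-RMSE improvement
#'   of more than `stopping_tol` before boosting stops (default 10).
#' @param stopping_tol improvement tolerance (default 1e-9).
#' @export
gbm_config <- function(ntree = 500, learning_rate = 0.05, max_depth = 3,
                       min_leaf = 5, stopping_rounds = 10,
                       stopping_tol = 1e-9) {
  stopifnot(ntree >= 0, learning_rate > 0, learning_rate <= 1, max_depth >= 1,
            min_leaf >= 1, stopping_rounds >= 1)
  structure(list(ntree = as.integer(ntree), learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf),
                 stopping_rounds = as.integer(stopping_rounds),
                 stopping_tol = stopping_tol), class = "gbm_config")
}

#' Fit a gradient-boosted tree ensemble
#'
#' Starts from the training mean and stage-wise fits depth-limited regression
#' trees to the current residuals by greedy variance-reduction splitting with
#' exact threshold enumeration (midpoints between distinct observed dosages).
#' Deterministic: no row or column subsampling; tie-breaking by lowest SNP
#' index then lowest threshold. The `seed` argument is accepted for interface
#' symmetry but unused.
#'
#' @param ystar training phenotype vector (named or not).
#' @param X dosage matrix, rows = training animals, columns named by SNP.
#' @param cfg a [gbm_config()].
#' @param seed ignored (the fit is deterministic).
#' @return object of class `c("gbm_fit", "gp_fit")`: `mu`, `trees` (list of
#'   node matrices), `rmse_trace`, `snp_ids`, `cfg`.
#' @export
fit_gbm <- function(ystar, X, cfg = gbm_config(), seed = NULL) {
  stopifnot(nrow(X) == length(ystar), !anyNA(ystar), !anyNA(X))
  if (nrow(X) < 2 * cfg$min_leaf && cfg$ntree > 0) {
    stop("need at least 2 * min_leaf training samples")
  }
  y <- as.numeric(ystar)
  if (stats::sd(y) == 0) {
    warning("constant phenotype: returning a zero-tree ensemble")
    res <- list(mu = mean(y), trees = list(), rmse_trace = numeric(0),
                train_pred = rep(mean(y), length(y)))
  } else {
    res <- .gbm_fit_cpp(y, X, cfg$ntree, cfg$learning_rate, cfg$max_depth,
                        cfg$min_leaf, cfg$stopping_rounds, cfg$stopping_tol)
  }
  structure(list(mu = res$mu, trees = res$trees, rmse_trace = res$rmse_trace,
                 train_pred = res$train_pred, snp_ids = colnames(X),
                 cfg = cfg),
            class = c("gbm_fit", "gp_fit"))
}

#' Predict from a tree ensemble
#'
#' @param object a `gbm_fit`.
#' @param X dosage matrix containing (at least) the training SNP columns.
#' @param ... unused.
#' @return named prediction vector `mu + sum_m learning_rate * h_m(x)`.
#' @export
predict.gbm_fit <- function(object, X, ...) {
  if (!all(object$snp_ids %in% colnames(X))) {
    stop("schema error: X lacks training SNP columns")
  }
  X <- X[, object$snp_ids, drop = FALSE]
  if (anyNA(X)) stop("X must be complete")
  stats::setNames(as.numeric(.gbm_predict_cpp(object$trees, object$mu,
                                              object$cfg$learning_rate, X)),
                  rownames(X))
}

#' Percentage-scale feature importance
#'
#' Accumulates each split's achieved squared-error reduction to its SNP across
#' all trees and normalizes to percentages summing to 100. SNPs never used
#' score 0; a zero-tree (or zero-split) ensemble yields all-zero scores with
#' attribute `no_splits = TRUE`.
#'
#' @param fit a `gbm_fit`.
#' @return data.frame (snp_id, importance_pct, rank), importance-descending,
#'   with the raw percentage vector in attribute `"scores"` (named by SNP, in
#'   panel order).
#' @export
feature_importance <- function(fit) {
  stopifnot(inherits(fit, "gbm_fit"))
  gain <- stats::setNames(numeric(length(fit$snp_ids)), fit$snp_ids)
  for (tm in fit$trees) {
    splits <- tm[, "feature"] > 0
    if (any(splits)) {
      f <- tm[splits, "feature"]
      g <- tm[splits, "gain"]
      agg <- tapply(g, f, sum)
      gain[as.integer(names(agg))] <- gain[as.integer(names(agg))] + agg
    }
  }
  total <- sum(gain)
  if (total <= 0) {
    out <- data.frame(snp_id = fit$snp_ids, importance_pct = 0,
                      rank = seq_along(fit$snp_ids))
    attr(out, "no_splits") <- TRUE
    attr(out, "scores") <- gain
    return(out)
  }
  pct <- 100 * gain / total
  ord <- order(-pct, names(pct))
  out <- data.frame(snp_id = names(pct)[ord], importance_pct = unname(pct[ord]),
                    rank = seq_along(pct))
  attr(out, "no_splits") <- FALSE
  attr(out, "scores") <- pct
  attr(out, "n_nonzero") <- sum(pct > 0)
  out
}

#' Grid-search tuning for the GBM
#'
#' Uses the same seeded 80-20 reference split as [tune_enet()]; the
#' configuration with the lowest held-out MSE wins (ties broken by fewer trees,
#' then shallower depth, then smaller learning rate) and is refit on the full
#' reference set.
#'
#' @param ystar named reference phenotype vector.
#' @param X dosage matrix with rownames = animal ids.
#' @param ntree_grid,lr_grid,depth_grid hyperparameter grids; defaults are the
#'   full study grids (8 x 3 x 4 combinations).
#' @param seed integer seed for the split.
#' @param ... further arguments to [gbm_config()] (min_leaf, stopping rules).
#' @return list with `fit` (refit winner), `best` config, and `grid`
#'   (data.frame of all combinations with held-out MSE).
#' @export
tune_gbm <- function(ystar, X,
                     ntree_grid = c(100, 150, 200, 300, 500, 1000, 2000, 5000),
                     lr_grid = c(0.01, 0.05, 0.10),
                     depth_grid = c(2, 3, 5, 10),
                     seed = 1, ...) {
  ids <- names(ystar)
  stopifnot(!is.null(ids), length(ids) >= 10, identical(rownames(X), ids))
  sp <- split_80_20(ids, seed = seed)
  tries <- 0
  while (stats::sd(ystar[sp$test]) == 0 && tries < 10) {
    tries <- tries + 1
    message("degenerate split (constant test phenotype); resampling with seed ",
            seed + tries)
    sp <- split_80_20(ids, seed = seed + tries)
  }
  ytr <- ystar[sp$train]; yte <- ystar[sp$test]
  Xtr <- X[sp$train, , drop = FALSE]; Xte <- X[sp$test, , drop = FALSE]
  grid <- expand.grid(ntree = ntree_grid, learning_rate = lr_grid,
                      max_depth = depth_grid)
  grid$mse <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    cfg <- gbm_config(ntree = grid$ntree[i],
                      learning_rate = grid$learning_rate[i],
                      max_depth = grid$max_depth[i], ...)
    f <- fit_gbm(ytr, Xtr, cfg)
    mse <- mean((yte - predict(f, Xte))^2)
    grid$mse[i] <- mse
    key <- c(mse, grid$ntree[i], grid$max_depth[i], grid$learning_rate[i])
    if (is.null(best) || .lex_less(key, best$key)) {
      best <- list(cfg = cfg, key = key)
    }
  }
  list(fit = fit_gbm(ystar, X, best$cfg), best = best$cfg, grid = grid,
       split_seed = seed + tries)
}

# lexicographic strict less-than over numeric keys
.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}
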