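#' Fit a generalized regression neural network (GRNN)
#'
#' A GRNN is a Nadaraya-Watson kernel regressor: training is pure
#' memorization (one pattern unit per training sample) and prediction is
#' a Gaussian-kernel-weighted average of the stored outputs,
#' \deqn{\hat Y(x) = \frac{\sum_i Y_i \exp(-D_i^2 / 2\sigma^2)}
#'                        {\sum_i \exp(-D_i^2 / 2\sigma^2)},}
#' with \eqn{D_i^2} the squared Euclidean distance between the query and
#' pattern unit \eqn{i}. The spread \eqn{\sigma} is the single free
#' parameter. Any output dimensionality is supported; a multi-output
#' GRNN with shared spread is mathematically identical to independent
#' per-output GRNNs with the same spread.
#'
#' @param X Training inputs, samples x features.
#' @param Y Training outputs, samples x outputs (or vector).
#' @param sigma Spread constant, > 0.
#' @return An object of class `grnn`.
#' @export
grnn_fit <- function(X, Y, sigma) {
  X <- as_matrix(X); Y <- as_matrix(Y)
  if (nrow(X) == 0L) stop_input("empty training set")
  if (nrow(X) != nrow(Y)) stop_input("X and Y row counts differ")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop_input("sigma must be a single positive number")
  }
  structure(list(X = X, Y = Y, sigma = sigma), class = "grnn")
}

#' Predict with a GRNN
#'
#' Evaluates the kernel-weighted average per query row. Exponents are
#' stabilized by subtracting the row-wise maximum before exponentiation,
#' so the nearest pattern unit always carries weight 1; should all
#' weights still underflow, the nearest pattern unit's output is
#' returned. Queries are processed in chunks to bound memory.
#'
#' @param model A [grnn_fit()] result.
#' @param Xq Query matrix, rows x same feature count as training.
#' @param chunk Maximum query rows per distance-matrix block.
#' @return Matrix of predictions, `nrow(Xq)` x outputs.
#' @export
grnn_predict <- function(model, Xq, chunk = 2000L) {
  Xq <- as_matrix(Xq)
  if (ncol(Xq) != ncol(model$X)) {
    stop_input("query dimensionality (", ncol(Xq), ") does not match training (",
               ncol(model$X), ")")
  }
  n <- nrow(Xq)
  out <- matrix(NA_real_, n, ncol(model$Y))
  colnames(out) <- colnames(model$Y)
  tr_sq <- rowSums(model$X^2)
  inv2s2 <- 1 / (2 * model$sigma^2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    Q <- Xq[idx, , drop = FALSE]
    d2 <- outer(rowSums(Q^2), tr_sq, "+") - 2 * Q %*% t(model$X)
    d2[d2 < 0] <- 0
    logw <- -d2 * inv2s2
    logw <- logw - apply(logw, 1, max)
    w <- exp(logw)
    denom <- rowSums(w)
    pred <- (w %*% model$Y) / denom
    bad <- !is.finite(denom) | denom == 0
    if (any(bad)) {
      nn <- apply(d2[bad, , drop = FALSE], 1, which.min)
      pred[bad, ] <- model$Y[nn, , drop = FALSE]
    }
    out[idx, ] <- pred
  }
  out
}

#' nu-SVR configuration (RBF kernel)
#'
#' @param nu Fraction-of-support-vectors control, in (0, 1].
#' @param cost Penalty parameter C, > 0.
#' @param sigma_rbf RBF kernel bandwidth: `k(x, y) = exp(-||x-y||^2 /
#'   (2 sigma_rbf^2))`.
#' @return An `fmg_svr_config`.
#' @export
svr_config <- function(nu = 0.5, cost = 10, sigma_rbf = 1) {
  if (nu <= 0 || nu > 1) stop_config("nu must lie in (0, 1]")
  if (cost <= 0) stop_config("cost must be positive")
  if (sigma_rbf <= 0) stop_config("sigma_rbf must be positive")
  structure(list(nu = nu, cost = cost, sigma_rbf = sigma_rbf),
            class = "fmg_svr_config")
}

#' Fit nu-SVR on one output column and predict
#'
#' Wraps [e1071::svm()] in nu-regression mode with an RBF kernel
#' (`gamma = 1 / (2 sigma_rbf^2)` matches the bandwidth convention of
#' [svr_config()]). One model per output axis. Deterministic given data
#' and configuration.
#'
#' @param cfg An [svr_config()].
#' @param X Training inputs.
#' @param y Training output column.
#' @param Xq Query inputs.
#' @return Numeric vector of predictions for `Xq`.
#' @export
svr_fit_predict <- function(cfg, X, y, Xq) {
  X <- as_matrix(X); Xq <- as_matrix(Xq)
  if (!all(is.finite(X)) || !all(is.finite(y)) || !all(is.finite(Xq))) {
    stop_input("non-finite values in SVR inputs")
  }
  if (stats::var(as.numeric(y)) == 0) {
    # constant target: the solver returns an empty model; the regression
    # function is the constant itself
    return(rep(y[1], nrow(Xq)))
  }
  fit <- e1071::svm(x = X, y = as.numeric(y), type = "nu-regression",
                    kernel = "radial", gamma = 1 / (2 * cfg$sigma_rbf^2),
                    cost = cfg$cost, nu = cfg$nu, scale = FALSE)
  as.numeric(stats::predict(fit, Xq))
}

#' Random-forest regression configuration
#'
#' @param n_trees Number of trees B, >= 1.
#' @param mtry Features tried per split; `NULL` for the implementation
#'   default (p/3 for regression).
#' @param nodesize Minimum terminal node size.
#' @param bootstrap Draw bootstrap samples per tree (TRUE) or use the
#'   full training set (FALSE).
#' @return An `fmg_rf_config`.
#' @export
rf_config <- function(n_trees = 100, mtry = NULL, nodesize = 5, bootstrap = TRUE) {
  if (n_trees < 1) stop_config("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 nodesize = nodesize, bootstrap = isTRUE(bootstrap)),
            class = "fmg_rf_config")
}

#' Fit a random forest on one output column and predict
#'
#' Ensemble mean over B trees via [randomForest::randomForest()]. The
#' seed fixes bootstrap and feature-subset randomness, making predictions
#' reproducible.
#'
#' @param cfg An [rf_config()].
#' @param X Training inputs.
#' @param y Training output column.
#' @param Xq Query inputs.
#' @param seed Integer RNG seed.
#' @param return_model Also return the fitted forest.
#' @return Numeric predictions, or `list(pred, model)` when
#'   `return_model = TRUE`.
#' @export
rf_fit_predict <- function(cfg, X, y, Xq, seed = 1L, return_model = FALSE) {
  X <- as_matrix(X); Xq <- as_matrix(Xq)
  mtry <- if (is.null(cfg$mtry)) max(floor(ncol(X) / 3), 1) else cfg$mtry
  fit <- with_seed(seed, randomForest::randomForest(
    x = X, y = as.numeric(y), ntree = cfg$n_trees, mtry = mtry,
    nodesize = cfg$nodesize, replace = cfg$bootstrap,
    sampsize = if (cfg$bootstrap) nrow(X) else nrow(X)
  ))
  pred <- as.numeric(stats::predict(fit, Xq))
  if (return_model) list(pred = pred, model = fit) else pred
}

#' Default hyperparameter grid per algorithm
#'
#' GRNN: 10 log-spaced spreads in \[0.01, 1\] (features are min-max
#' normalized). SVR: nu in \{0.25, 0.5, 0.75\}, C in \{1, 10, 100\},
#' RBF bandwidth in \{0.1, 1, 10\}. RF: 50/100/200 trees with node sizes
#' 1/5/10.
#'
#' @param algorithm `"grnn"`, `"svr"` or `"rf"`.
#' @return A data.frame, one row per grid point.
#' @export
default_grid <- function(algorithm = c("grnn", "svr", "rf")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    grnn = data.frame(sigma = 10^seq(log10(0.01), log10(1), length.out = 10)),
    svr = expand.grid(nu = c(0.25, 0.5, 0.75), cost = c(1, 10, 100),
                      sigma_rbf = c(0.1, 1, 10)),
    rf = expand.grid(n_trees = c(50, 100, 200), nodesize = c(1, 5, 10))
  )
}

#' Tuning plan: k-fold cross-validated grid search
#'
#' @param grid Data frame of hyperparameter candidates (one column per
#'   parameter); `NULL` uses [default_grid()] at tune time.
#' @param n_folds Number of CV folds (10 by default).
#' @param fold_type `"shuffled"` (random assignment under the plan seed)
#'   or `"blocked"` (contiguous blocks, for temporal-leakage studies).
#' @param seed Seed for the fold shuffle.
#' @param grid_stage2 Optional GRNN spread grid for the stacking second
#'   stage; `NULL` uses the default GRNN grid.
#' @return An `fmg_tuning_plan`.
#' @export
tuning_plan <- function(grid = NULL, n_folds = 10L,
                        fold_type = c("shuffled", "blocked"), seed = 1L,
                        grid_stage2 = NULL) {
  fold_type <- match.arg(fold_type)
  if (!is.null(grid) && nrow(grid) == 0L) stop_config("grid must be nonempty")
  structure(list(grid = grid, n_folds = as.integer(n_folds),
                 fold_type = fold_type, seed = as.integer(seed),
                 grid_stage2 = grid_stage2),
            class = "fmg_tuning_plan")
}

make_folds <- function(n, plan) {
  k <- min(plan$n_folds, n)
  if (plan$fold_type == "blocked") {
    sort(rep(seq_len(k), length.out = n))
  } else {
    with_seed(plan$seed, sample(rep(seq_len(k), length.out = n)))
  }
}

fit_predict_one <- function(algorithm, params, X, Y, Xq, seed = 1L) {
  Y <- as_matrix(Y)
  if (algorithm == "grnn") {
    grnn_predict(grnn_fit(X, Y, params$sigma), Xq)
  } else {
    preds <- sapply(seq_len(ncol(Y)), function(j) {
      if (algorithm == "svr") {
        svr_fit_predict(svr_config(params$nu, params$cost, params$sigma_rbf),
                        X, Y[, j], Xq)
      } else {
        rf_fit_predict(rf_config(params$n_trees, nodesize = params$nodesize),
                       X, Y[, j], Xq, seed = sub_seed(seed, j))
      }
    })
    as_matrix(preds)
  }
}

# Smoothness rank used to break MSE ties toward the smoother model:
# larger GRNN spread, larger RBF bandwidth then smaller C, fewer trees.
smoothness_order <- function(algorithm, grid) {
  switch(algorithm,
    grnn = order(-grid$sigma),
    svr = order(-grid$sigma_rbf, grid$cost, grid$nu),
    rf = order(grid$n_trees, -grid$nodesize)
  )
}

#' Grid-search hyperparameters by k-fold cross-validation
#'
#' Exhaustively scores every grid point by mean validation MSE (averaged
#' over folds and output dimensions) and returns the minimizer; ties
#' (within 1e-12) break toward the smoothest model.
#'
#' @param plan An [tuning_plan()].
#' @param algorithm `"grnn"`, `"svr"` or `"rf"`.
#' @param X Training inputs.
#' @param Y Training outputs (matrix or vector).
#' @return List with `best` (named list of the chosen parameters) and
#'   `table` (grid with a `mean_mse` column).
#' @export
tune <- function(plan, algorithm = c("grnn", "svr", "rf"), X, Y) {
  algorithm <- match.arg(algorithm)
  X <- as_matrix(X); Y <- as_matrix(Y)
  if (nrow(X) < plan$n_folds) stop_input("need at least n_folds training samples")
  grid <- if (is.null(plan$grid)) default_grid(algorithm) else plan$grid
  if (nrow(grid) == 1L) {
    return(list(best = as.list(grid[1, , drop = FALSE]),
                table = cbind(grid, mean_mse = NA_real_)))
  }
  folds <- make_folds(nrow(X), plan)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    fold_mse <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      pred <- fit_predict_one(algorithm, params,
                              X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                              X[!tr, , drop = FALSE],
                              seed = sub_seed(plan$seed, f))
      mean((pred - Y[!tr, , drop = FALSE])^2)
    }, numeric(1))
    mean(fold_mse)
  }, numeric(1))
  if (all(!is.finite(scores))) stop_input("all grid points failed")
  ord <- smoothness_order(algorithm, grid)
  best_score <- min(scores, na.rm = TRUE)
  best_idx <- ord[which(scores[ord] <= best_score + 1e-12)[1]]
  list(best = as.list(grid[best_idx, , drop = FALSE]),
       table = cbind(grid, mean_mse = scores))
}
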