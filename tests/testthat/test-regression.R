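test_that("GRNN stores one pattern unit per training sample and validates inputs", {
  X <- matrix(rnorm(40), 20, 2); Y <- matrix(rnorm(40), 20, 2)
  m <- grnn_fit(X, Y, 0.5)
  expect_equal(nrow(m$X), 20)
  expect_identical(grnn_fit(X, Y, 0.5), m) # deterministic memorization
  expect_error(grnn_fit(X, Y, 0), class = "fmg_input_error")
  expect_error(grnn_fit(X[0, , drop = FALSE], Y[0, , drop = FALSE], 1),
               class = "fmg_input_error")
  expect_error(grnn_predict(m, matrix(0, 1, 3)), class = "fmg_input_error")
})

test_that("GRNN prediction matches hand-evaluated kernel averages", {
  # single pattern unit: any query returns its output
  m1 <- grnn_fit(matrix(0.3), matrix(3.7), sigma = 2)
  expect_equal(as.numeric(grnn_predict(m1, matrix(99))), 3.7)
  # two units at 0 and 1, outputs 0 and 2, sigma 1, query at 0:
  # (0 + 2 e^-0.5) / (1 + e^-0.5)
  m2 <- grnn_fit(matrix(c(0, 1)), matrix(c(0, 2)), sigma = 1)
  expect_equal(as.numeric(grnn_predict(m2, matrix(0))),
               2 * exp(-0.5) / (1 + exp(-0.5)), tolerance = 1e-12)
  # equidistant query returns the mean of the two outputs
  expect_equal(as.numeric(grnn_predict(m2, matrix(0.5))), 1, tolerance = 1e-12)
})

test_that("stabilized GRNN matches the literal kernel-average transcription", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(10:50, 1); d <- sample(1:5, 1)
    X <- matrix(rnorm(n * d), n, d)
    Y <- matrix(rnorm(n * 2), n, 2)
    Xq <- matrix(rnorm(8 * d), 8, d)
    sigma <- runif(1, 0.3, 3)
    expect_equal(unname(grnn_predict(grnn_fit(X, Y, sigma), Xq)),
                 grnn_reference(X, Y, sigma, Xq), tolerance = 1e-10)
  }
})

test_that("GRNN predictions are convex combinations of the training outputs", {
  set.seed(22)
  X <- matrix(rnorm(60), 30, 2); Y <- matrix(rnorm(60), 30, 2)
  Xq <- matrix(rnorm(40) * 3, 20, 2)
  for (s in c(0.05, 0.5, 5)) {
    p <- grnn_predict(grnn_fit(X, Y, s), Xq)
    for (j in 1:2) {
      expect_true(all(p[, j] >= min(Y[, j]) - 1e-12))
      expect_true(all(p[, j] <= max(Y[, j]) + 1e-12))
    }
  }
})

test_that("GRNN tends to the training mean as the spread grows", {
  set.seed(23)
  X <- matrix(runif(50), 25, 2); Y <- matrix(runif(50), 25, 2)
  p <- grnn_predict(grnn_fit(X, Y, 1e6), matrix(runif(10), 5, 2))
  expect_equal(p, matrix(colMeans(Y), 5, 2, byrow = TRUE), tolerance = 1e-6)
})

test_that("GRNN far-query fallback returns a finite nearby label", {
  m <- grnn_fit(matrix(c(0, 1)), matrix(c(0, 2)), sigma = 1e-4)
  p <- grnn_predict(m, matrix(1e6))
  expect_true(is.finite(p))
  expect_equal(as.numeric(p), 2) # nearest pattern unit
})

test_that("nu-SVR respects constant targets and learns a linear map", {
  set.seed(24)
  X <- matrix(rnorm(200), 100, 2)
  # constant target: predictions within the epsilon tube of the constant
  p <- svr_fit_predict(svr_config(0.5, 10, 1), X, rep(2, 100), X)
  expect_true(all(abs(p - 2) < 0.2))
  # linear target, low noise: held-out R2 >= 0.95
  Xall <- matrix(rnorm(1000), 500, 2)
  y <- Xall %*% c(1.5, -2) + rnorm(500, 0, 0.01)
  tr <- 1:350
  p2 <- svr_fit_predict(svr_config(0.5, 10, 2), Xall[tr, ], y[tr], Xall[-tr, ])
  expect_gte(r_squared(y[-tr], p2), 0.95)
  # duplicated rows do not break anything
  Xd <- Xall[c(1:50, 1:50), ]; yd <- y[c(1:50, 1:50)]
  expect_true(all(is.finite(svr_fit_predict(svr_config(), Xd, yd, Xd[1:5, ]))))
  expect_error(svr_fit_predict(svr_config(), cbind(c(1, NA)), 1:2, cbind(1)),
               class = "fmg_input_error")
})

test_that("random forest is a seeded ensemble mean over trees", {
  set.seed(25)
  X <- matrix(rnorm(300), 100, 3)
  y <- X %*% c(1, 0.5, -1) + rnorm(100, 0, 0.05)
  cfg <- rf_config(n_trees = 25)
  p1 <- rf_fit_predict(cfg, X, y, X[1:10, ], seed = 7)
  p2 <- rf_fit_predict(cfg, X, y, X[1:10, ], seed = 7)
  expect_identical(p1, p2)
  # ensemble mean equals the brute-force average of per-tree predictions
  fit <- rf_fit_predict(cfg, X, y, X[1:10, ], seed = 7, return_model = TRUE)
  per_tree <- predict(fit$model, X[1:10, ], predict.all = TRUE)$individual
  expect_equal(fit$pred, unname(rowMeans(per_tree)), tolerance = 1e-12)
  # single unbootstrapped deep tree interpolates distinct training points
  cfg1 <- rf_config(n_trees = 1, mtry = 3, nodesize = 1, bootstrap = FALSE)
  p3 <- rf_fit_predict(cfg1, X, y, X, seed = 3)
  expect_equal(p3, as.numeric(y), tolerance = 1e-8)
  expect_error(rf_config(n_trees = 0), class = "fmg_config_error")
})

test_that("grid search scores by mean validation MSE and is reproducible", {
  set.seed(26)
  X <- matrix(runif(400), 200, 2)
  y <- sin(4 * X[, 1]) + 0.5 * X[, 2] + rnorm(200, 0, 0.05)
  grid <- data.frame(sigma = 10^seq(-2, 0, length.out = 5))
  plan <- tuning_plan(grid, n_folds = 10, seed = 4)
  t1 <- tune(plan, "grnn", X, y)
  t2 <- tune(plan, "grnn", X, y)
  expect_identical(t1$best, t2$best)
  # the selected spread minimizes the recorded CV score
  expect_equal(t1$table$mean_mse[which(grid$sigma == t1$best$sigma)],
               min(t1$table$mean_mse))
  # interior optimum on a smooth noiseless target
  yq <- sin(4 * X[, 1])
  t3 <- tune(plan, "grnn", X, yq)
  expect_true(t3$best$sigma > min(grid$sigma) && t3$best$sigma < max(grid$sigma))
  # single-point grids short-circuit to that point
  t4 <- tune(tuning_plan(data.frame(sigma = 0.2)), "grnn", X, y)
  expect_equal(t4$best$sigma, 0.2)
})

test_that("tuning ties break toward the smoother model", {
  # constant target: every spread scores identically, largest sigma wins
  X <- matrix(seq(0, 1, length.out = 40), ncol = 1)
  y <- rep(1, 40)
  grid <- data.frame(sigma = c(0.01, 0.1, 1))
  best <- tune(tuning_plan(grid, n_folds = 5, seed = 2), "grnn", X, y)$best
  expect_equal(best$sigma, 1)
})
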