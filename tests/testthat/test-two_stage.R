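make_prepped <- function(seed = 61, n_trials = 3, duration = 6) {
  ds <- make_test_subject(seed = seed, n_trials = n_trials, duration = duration)
  ds <- preprocess_subject(ds, test_spec())
  ds
}

split_norm <- function(ds, held = max(ds$trial_id)) {
  tr_idx <- which(ds$trial_id != held)
  te_idx <- which(ds$trial_id == held)
  train <- ds; test <- ds
  train$fmg <- ds$fmg[tr_idx, ]; train$labels <- ds$labels[tr_idx, ]
  train$trial_id <- ds$trial_id[tr_idx]; train$session_id <- ds$session_id[tr_idx]
  test$fmg <- ds$fmg[te_idx, ]; test$labels <- ds$labels[te_idx, ]
  test$trial_id <- ds$trial_id[te_idx]; test$session_id <- ds$session_id[te_idx]
  ref <- fit_normalizer(train$fmg)
  train$fmg <- apply_normalizer(ref, train$fmg)
  test$fmg <- apply_normalizer(ref, test$fmg)
  list(train = train, test = test, ref = ref)
}

plan_fixed <- tuning_plan(grid = data.frame(sigma = 0.1), seed = 1,
                          grid_stage2 = data.frame(sigma = 0.3))

test_that("case configurations define outputs, sessions, and a GRNN second stage", {
  c1f <- case_config(1, "force", "svr")
  expect_equal(c1f$outputs, c("Fx", "Fy", "Fz"))
  expect_equal(c1f$sessions, c("Fx", "Fy", "Fz"))
  c1t <- case_config(1, "torque")
  expect_equal(c1t$outputs, c("Tx", "Ty", "Tz"))
  c2 <- case_config(2)
  expect_equal(c2$outputs, FMG_AXES)
  expect_true("free" %in% c2$sessions)
  expect_equal(c2$stage2_algorithm, "grnn")
  expect_error(case_config(3), class = "fmg_config_error")
})

test_that("case-2 fit yields six stage-1 outputs and one multi-output stage-2 GRNN", {
  sp <- split_norm(make_prepped())
  m <- fit_two_stage(sp$train, case_config(2, stage1_algorithm = "grnn"),
                     plan_fixed, norm_ref = sp$ref)
  expect_equal(ncol(m$stage1$model$Y), 6)
  expect_s3_class(m$stage2, "grnn")
  expect_equal(ncol(m$stage2$Y), 6)
  # stage-2 feature count: 2 * 60 channels + 6 + 6 + 6
  expect_equal(ncol(m$stage2$X), 2 * 60 + 18)
  pred <- predict_two_stage(m, sp$test)
  expect_equal(colnames(pred$stage2), FMG_AXES)
  expect_equal(nrow(pred$stage2), nrow(sp$test$fmg))
})

test_that("case-1 force restricts training to force sessions with three outputs", {
  sp <- split_norm(make_prepped())
  m <- fit_two_stage(sp$train, case_config(1, "force", "grnn"), plan_fixed)
  expect_equal(ncol(m$stage1$model$Y), 3)
  # 2 trials x 3 force sessions x 60 samples
  expect_equal(nrow(m$stage1$model$X), 2 * 3 * 60)
  pred <- predict_two_stage(m, sp$test)
  expect_equal(colnames(pred$stage2), c("Fx", "Fy", "Fz"))
})

test_that("refitting with the same seed reproduces stage-2 training features", {
  sp <- split_norm(make_prepped())
  cfg <- case_config(2, stage1_algorithm = "grnn")
  m1 <- fit_two_stage(sp$train, cfg, plan_fixed)
  m2 <- fit_two_stage(sp$train, cfg, plan_fixed)
  expect_identical(m1$stage2_train_features, m2$stage2_train_features)
  expect_identical(m1$tuned1, m2$tuned1)
})

test_that("no training step sees test data", {
  ds <- make_prepped(seed = 62)
  sp <- split_norm(ds)
  cfg <- case_config(2, stage1_algorithm = "grnn")
  m <- fit_two_stage(sp$train, cfg, plan_fixed, norm_ref = sp$ref)
  # normalization statistics recompute from training trials alone
  expect_identical(m$norm_ref$min,
                   apply(preprocess_subject(make_test_subject(62, 3, 6),
                                            test_spec())$fmg[ds$trial_id != 3, ],
                         2, min))
  # stage-2 pattern units span exactly the training rows
  expect_equal(nrow(m$stage2$X), nrow(sp$train$fmg))
  # perturbing the held-out trial leaves the fitted model unchanged
  sp2 <- sp
  sp2$test$fmg <- sp2$test$fmg * 2
  m2 <- fit_two_stage(sp2$train, cfg, plan_fixed, norm_ref = sp$ref)
  expect_identical(m$stage2$X, m2$stage2$X)
})

test_that("in-sample stage-2 features reproduce bit-exactly when re-deriving on training data", {
  sp <- split_norm(make_prepped(seed = 63))
  cfg <- case_config(2, stage1_algorithm = "grnn")
  m <- fit_two_stage(sp$train, cfg, plan_fixed, stage2_train = "insample")
  pred_tr <- predict_two_stage(m, sp$train)
  X2 <- apply_normalizer(
    m$feature_norm2,
    assemble_features(m$recipe2, sp$train$fmg,
                      stage1_pred = pred_tr$stage1,
                      trial_id = sp$train$trial_id))
  expect_equal(unname(X2), unname(m$stage2_train_features), tolerance = 1e-12)
})

test_that("channel mismatch between training and test is a labeled error", {
  sp <- split_norm(make_prepped(seed = 64))
  m <- fit_two_stage(select_bands(sp$train, 3), case_config(2), plan_fixed)
  expect_error(predict_two_stage(m, sp$test), class = "fmg_input_error")
})

test_that("missing case sessions are a labeled error", {
  sp <- split_norm(make_prepped(seed = 65))
  only_force <- sp$train
  keep <- only_force$session_id %in% c("Fx", "Fy", "Fz")
  only_force$fmg <- only_force$fmg[keep, ]
  only_force$labels <- only_force$labels[keep, ]
  only_force$trial_id <- only_force$trial_id[keep]
  only_force$session_id <- only_force$session_id[keep]
  expect_error(fit_two_stage(only_force, case_config(1, "torque"), plan_fixed),
               class = "fmg_input_error")
})
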