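#' Case configuration for the stacked regression
#'
#' Case 1 trains separate 3-DoF models: a force model on the three
#' force-focused sessions predicting (Fx, Fy, Fz), and a torque model on
#' the three torque-focused sessions predicting (Tx, Ty, Tz). Case 2
#' trains one 6-DoF model on all sessions, including the free-exertion
#' session. The second stage is always a multi-output GRNN.
#'
#' @param case 1 or 2.
#' @param target For case 1: `"force"` or `"torque"`.
#' @param stage1_algorithm `"grnn"`, `"svr"` or `"rf"`.
#' @return An `fmg_case`.
#' @export
case_config <- function(case = 2L, target = c("force", "torque"),
                        stage1_algorithm = c("grnn", "svr", "rf")) {
  stage1_algorithm <- match.arg(stage1_algorithm)
  if (!case %in% 1:2) stop_config("case must be 1 or 2")
  if (case == 1L) {
    target <- match.arg(target)
    outputs <- if (target == "force") FMG_AXES[1:3] else FMG_AXES[4:6]
    sessions <- outputs
  } else {
    target <- "all"
    outputs <- FMG_AXES
    sessions <- c(FMG_AXES, "free")
  }
  structure(list(case = as.integer(case), target = target, outputs = outputs,
                 sessions = sessions, stage1_algorithm = stage1_algorithm,
                 stage2_algorithm = "grnn"),
            class = "fmg_case")
}

slice_sessions <- function(ds, sessions) {
  idx <- which(ds$session_id %in% sessions)
  if (length(idx) == 0L) {
    stop_input("dataset has none of the sessions required by this case: ",
               paste(sessions, collapse = ", "))
  }
  subset_rows(ds, idx)
}

#' Fit the two-stage stacked regression model
#'
#' Stage 1 tunes (by the plan's k-fold grid search) and fits one model
#' per output axis on the stage-1 features (normalized FMG + derivative);
#' GRNN uses a single multi-output model with shared spread, which is
#' equivalent to per-axis models. The stage-1 models are then applied to
#' the same training data, and their in-sample predictions are assembled
#' with the FMG block, prediction derivatives and the spherical
#' transform into stage-2 features, on which a multi-output GRNN is
#' tuned and fit against the same true labels. Test data never enters
#' any training step.
#'
#' @param train An `fmg_subject` slice, already band-selected, filtered
#'   and min-max normalized; must contain at least 2 trials and the
#'   case's sessions.
#' @param cfg An [case_config()].
#' @param plan An [tuning_plan()].
#' @param norm_ref The normalizer used on `train`, stored for provenance.
#' @param stage2_train How the stage-1 training predictions fed to stage
#'   2 are produced. `"insample"` (default) applies the final stage-1
#'   models to their own training data; `"crossfit"` uses out-of-fold
#'   predictions with training trials as folds, so the stage-2 learner
#'   sees stage-1 outputs with out-of-sample error. With few training
#'   trials the cross-fitted predictions are substantially noisier than
#'   the final stage-1 models' test-time output, so in-sample is the
#'   default; prefer cross-fitting when stage 1 memorizes (tiny GRNN
#'   spread chosen by shuffled-fold tuning).
#' @return An `fmg_two_stage` model.
#' @export
fit_two_stage <- function(train, cfg, plan = tuning_plan(), norm_ref = NULL,
                          stage2_train = c("insample", "crossfit")) {
  stage2_train <- match.arg(stage2_train)
  train <- slice_sessions(train, cfg$sessions)
  trials <- sort(unique(train$trial_id))
  if (stage2_train == "crossfit" && length(trials) < 2L) {
    stop_input("cross-fitted stage-2 training needs at least 2 training trials")
  }
  Y <- train$labels[, cfg$outputs, drop = FALSE]
  r1 <- feature_recipe(1)
  X1raw <- assemble_features(r1, train$fmg, trial_id = train$trial_id)
  # feature blocks live on different scales (normalized FMG in [0,1],
  # derivatives an order of magnitude smaller, predictions in N / Nm);
  # min-max normalization from training statistics puts them on a common
  # scale so a single kernel bandwidth is meaningful across blocks
  fnorm1 <- suppressWarnings(fit_normalizer(X1raw))
  X1 <- apply_normalizer(fnorm1, X1raw)

  tuned1 <- tune(plan, cfg$stage1_algorithm, X1, Y)
  stage1 <- fit_stage1(cfg$stage1_algorithm, tuned1$best, X1, Y, seed = plan$seed)
  if (stage2_train == "insample") {
    P_train <- predict_stage1(stage1, X1)
  } else {
    P_train <- matrix(NA_real_, nrow(X1), length(cfg$outputs))
    for (u in trials) {
      hold <- train$trial_id == u
      s1 <- fit_stage1(cfg$stage1_algorithm, tuned1$best,
                       X1[!hold, , drop = FALSE], Y[!hold, , drop = FALSE],
                       seed = sub_seed(plan$seed, 100L + u))
      P_train[hold, ] <- predict_stage1(s1, X1[hold, , drop = FALSE])
    }
  }
  colnames(P_train) <- paste0("pred_", cfg$outputs)

  r2 <- feature_recipe(2)
  X2raw <- assemble_features(r2, train$fmg, stage1_pred = P_train,
                             trial_id = train$trial_id)
  fnorm2 <- suppressWarnings(fit_normalizer(X2raw))
  X2 <- apply_normalizer(fnorm2, X2raw)
  plan2 <- tuning_plan(plan$grid_stage2, plan$n_folds, plan$fold_type,
                       seed = sub_seed(plan$seed, 2L))
  tuned2 <- tune(plan2, "grnn", X2, Y)
  stage2 <- grnn_fit(X2, Y, tuned2$best$sigma)

  structure(
    list(cfg = cfg, stage1 = stage1, stage2 = stage2,
         recipe1 = r1, recipe2 = r2,
         feature_norm1 = fnorm1, feature_norm2 = fnorm2,
         tuned1 = tuned1$best, tuned2 = tuned2$best,
         norm_ref = norm_ref, n_channels = ncol(train$fmg),
         stage2_train = stage2_train,
         stage2_train_features = X2),
    class = "fmg_two_stage"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_stage1 <- function(algorithm, params, X, Y, seed = 1L) {
  Y <- as_matrix(Y)
  if (algorithm == "grnn") {
    list(algorithm = "grnn", model = grnn_fit(X, Y, params$sigma))
  } else if (algorithm == "svr") {
    models <- lapply(seq_len(ncol(Y)), function(j) {
      e1071::svm(x = X, y = Y[, j], type = "nu-regression", kernel = "radial",
                 gamma = 1 / (2 * params$sigma_rbf^2),
                 cost = params$cost, nu = params$nu, scale = FALSE)
    })
    list(algorithm = "svr", models = models)
  } else {
    models <- lapply(seq_len(ncol(Y)), function(j) {
      mtry <- max(floor(ncol(X) / 3), 1)
      with_seed(sub_seed(seed, j), randomForest::randomForest(
        x = X, y = Y[, j], ntree = params$n_trees, mtry = mtry,
        nodesize = params$nodesize
      ))
    })
    list(algorithm = "rf", models = models)
  }
}

predict_stage1 <- function(stage1, Xq) {
  if (stage1$algorithm == "grnn") {
    grnn_predict(stage1$model, Xq)
  } else {
    as_matrix(sapply(stage1$models, function(m) as.numeric(stats::predict(m, Xq))))
  }
}

#' Predict with a fitted two-stage model
#'
#' Runs the stage-1 models on the test stage-1 features, assembles the
#' stage-2 features from the stage-1 test predictions, and returns both
#' the intermediate and the final (stage-2) predictions. All reported
#' accuracies use the final predictions.
#'
#' @param model An [fit_two_stage()] result.
#' @param test An `fmg_subject` slice preprocessed and normalized with
#'   the training statistics; channel set must match training.
#' @return List with `stage1` and `stage2` prediction matrices (columns
#'   in `model$cfg$outputs` order).
#' @export
predict_two_stage <- function(model, test) {
  test <- slice_sessions(test, model$cfg$sessions)
  if (ncol(test$fmg) != model$n_channels) {
    stop_input("test channel count (", ncol(test$fmg),
               ") does not match training (", model$n_channels, ")")
  }
  X1 <- apply_normalizer(
    model$feature_norm1,
    assemble_features(model$recipe1, test$fmg, trial_id = test$trial_id))
  P1 <- predict_stage1(model$stage1, X1)
  colnames(P1) <- paste0("pred_", model$cfg$outputs)
  X2 <- apply_normalizer(
    model$feature_norm2,
    assemble_features(model$recipe2, test$fmg, stage1_pred = P1,
                      trial_id = test$trial_id))
  P2 <- grnn_predict(model$stage2, X2)
  colnames(P1) <- model$cfg$outputs
  colnames(P2) <- model$cfg$outputs
  list(stage1 = P1, stage2 = P2)
}
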