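#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SST` with `SSE = sum((yhat - y)^2)` and
#' `SST = sum((y - mean(y))^2)`. May be negative (a model worse than the
#' mean predictor); values are never clamped.
#'
#' @param y_true Observed sequence (length >= 2, not constant).
#' @param y_pred Predicted sequence of equal length.
#' @return A single numeric R-squared.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_input("lengths differ")
  if (length(y_true) < 2L) stop_input("need at least 2 observations")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop_input("y_true is constant; R-squared undefined")
  1 - sum((y_pred - y_true)^2) / sst
}

#' Cross-trial (leave-one-trial-out) evaluation of the two-stage model
#'
#' For every trial in turn: band-select and filter the subject, hold the
#' trial out, learn min-max normalization from the remaining trials, tune
#' and fit the two-stage model on them, predict the held-out trial, and
#' score per-axis R-squared on both the stage-1 and the final stage-2
#' predictions. With k trials this is k-fold; fold results do not depend
#' on visiting order.
#'
#' @param ds An `fmg_subject` (raw; preprocessing happens inside).
#' @param cfg An [case_config()].
#' @param combo A [band_combination()].
#' @param plan An [tuning_plan()].
#' @param spec An [filter_spec()].
#' @param stage2_train Stage-2 training-prediction mode, see
#'   [fit_two_stage()].
#' @return A tibble with columns `trial`, `axis`, `r2_stage1`, `r2`
#'   (final), one row per held-out trial x output axis.
#' @export
cross_trial_evaluate <- function(ds, cfg = case_config(2),
                                 combo = band_combination(1:4),
                                 plan = tuning_plan(),
                                 spec = filter_spec(),
                                 stage2_train = "insample") {
  trials <- sort(unique(ds$trial_id))
  if (length(trials) < 2L) stop_input("cross-trial evaluation needs >= 2 trials")
  ds <- select_bands(ds, combo)
  ds <- preprocess_subject(ds, spec)
  ds <- slice_sessions(ds, cfg$sessions)
  res <- lapply(trials, function(held) {
    tr_idx <- ds$trial_id != held
    train <- subset_rows(ds, which(tr_idx))
    test <- subset_rows(ds, which(!tr_idx))
    ref <- fit_normalizer(train$fmg)
    train$fmg <- apply_normalizer(ref, train$fmg)
    test$fmg <- apply_normalizer(ref, test$fmg)
    model <- fit_two_stage(train, cfg, plan, norm_ref = ref,
                           stage2_train = stage2_train)
    pred <- predict_two_stage(model, test)
    truth <- test$labels[, cfg$outputs, drop = FALSE]
    tibble::tibble(
      trial = held,
      axis = cfg$outputs,
      r2_stage1 = vapply(seq_along(cfg$outputs), function(j)
        r_squared(truth[, j], pred$stage1[, j]), numeric(1)),
      r2 = vapply(seq_along(cfg$outputs), function(j)
        r_squared(truth[, j], pred$stage2[, j]), numeric(1))
    )
  })
  do.call(rbind, res)
}

#' Full band-combination x algorithm x case sweep
#'
#' Runs [cross_trial_evaluate()] for every subject, case, band
#' combination and stage-1 algorithm, and returns the fold-level results
#' in tidy long format. Per-subject means (over trials and axes) are the
#' observations entering the ANOVA of [two_way_anova()].
#'
#' @param subjects Named list of `fmg_subject` objects.
#' @param cases List of [case_config()] objects.
#' @param combos List of [band_combination()] objects (default all 15).
#' @param algorithms Character vector of stage-1 algorithms.
#' @param plan An [tuning_plan()].
#' @param spec An [filter_spec()].
#' @return A tibble with columns `subject`, `case`, `target`, `combo`,
#'   `algorithm`, `trial`, `axis`, `r2_stage1`, `r2`.
#' @export
sweep_evaluate <- function(subjects,
                           cases = list(case_config(2)),
                           combos = enumerate_combinations(),
                           algorithms = c("grnn", "svr", "rf"),
                           plan = tuning_plan(),
                           spec = filter_spec()) {
  if (length(subjects) < 1L) stop_input("need at least one subject")
  if (is.null(names(subjects))) {
    names(subjects) <- paste0("S", seq_along(subjects))
  }
  rows <- list()
  for (subj in names(subjects)) {
    for (cs in cases) {
      for (alg in algorithms) {
        cfg <- case_config(cs$case,
                           target = if (cs$case == 1) cs$target else "force",
                           stage1_algorithm = alg)
        for (cb in combos) {
          r <- cross_trial_evaluate(subjects[[subj]], cfg, cb, plan, spec)
          r$subject <- subj
          r$case <- cfg$case
          r$target <- cfg$target
          r$combo <- format(band_combination(cb))
          r$algorithm <- alg
          rows[[length(rows) + 1L]] <- r
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out[, c("subject", "case", "target", "combo", "algorithm",
          "trial", "axis", "r2_stage1", "r2")]
}

#' Aggregate fold-level results to per-subject means
#'
#' Averages R-squared over held-out trials and output axes within each
#' (subject, case, target, combo, algorithm) cell — the "3-DoF R2" /
#' "6-DoF R2" summaries.
#'
#' @param results Tidy fold-level tibble from [sweep_evaluate()] (or
#'   [cross_trial_evaluate()] plus the identifying columns).
#' @return A tibble with one `mean_r2` (and `mean_r2_stage1`) row per
#'   cell.
#' @export
aggregate_results <- function(results) {
  keys <- intersect(c("subject", "case", "target", "combo", "algorithm"),
                    names(results))
  dt <- data.table::as.data.table(results)
  agg <- dt[, list(mean_r2 = mean(r2), mean_r2_stage1 = mean(r2_stage1),
                   n_folds = length(unique(trial))), by = keys]
  tibble::as_tibble(agg)
}
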