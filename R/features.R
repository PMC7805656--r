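#' Temporal derivative (first difference) feature
#'
#' First difference per column with a leading 0 in the first row, so the
#' output keeps the input's shape. When `trial_id` is given, the
#' difference restarts at each trial boundary: the derivative never mixes
#' samples from different trials.
#'
#' @param x Samples x d matrix.
#' @param trial_id Optional per-sample trial labels.
#' @return Samples x d matrix.
#' @export
derivative <- function(x, trial_id = NULL) {
  x <- as_matrix(x)
  if (nrow(x) < 2L) stop_input("derivative needs at least 2 samples")
  d <- rbind(0, diff(x))
  if (!is.null(trial_id)) {
    starts <- which(c(TRUE, trial_id[-1] != trial_id[-length(trial_id)]))
    d[starts, ] <- 0
  }
  colnames(d) <- if (!is.null(colnames(x))) paste0(colnames(x), "_d") else NULL
  d
}

#' Spherical-coordinate transform of force/torque triples
#'
#' Each consecutive column triple `(x, y, z)` maps to `(r, theta, phi)`
#' in the ISO physics convention: radius `r = sqrt(x^2+y^2+z^2)`, polar
#' angle `theta = acos(z/r)` from the +Z axis (0 when `r = 0`), and
#' azimuth `phi = atan2(y, x)`. Angles are in radians. A 6-column input
#' (force triple, torque triple) yields 6 columns.
#'
#' @param m Samples x 3k matrix.
#' @return Samples x 3k matrix of spherical coordinates.
#' @export
spherical_transform <- function(m) {
  m <- as_matrix(m)
  if (ncol(m) %% 3L != 0L) stop_input("column count must be divisible by 3")
  if (!all(is.finite(m))) stop_input("input must be finite")
  out <- matrix(0, nrow(m), ncol(m))
  nm <- character(ncol(m))
  for (g in seq_len(ncol(m) / 3L)) {
    j <- (g - 1L) * 3L
    x <- m[, j + 1L]; y <- m[, j + 2L]; z <- m[, j + 3L]
    r <- sqrt(x^2 + y^2 + z^2)
    theta <- ifelse(r > 0, acos(pmin(pmax(z / pmax(r, .Machine$double.xmin), -1), 1)), 0)
    phi <- atan2(y, x)
    out[, j + 1:3] <- cbind(r, theta, phi)
    nm[j + 1:3] <- paste0(c("r", "theta", "phi"), g)
  }
  colnames(out) <- nm
  out
}

#' Feature recipe for a regression stage
#'
#' Stage 1 uses the normalized FMG channels plus their temporal
#' derivative. Stage 2 additionally appends the stage-1 predictions,
#' their derivative, and the spherical transform of the predicted
#' force/torque triples.
#'
#' @param stage 1 or 2.
#' @param include_raw,include_derivative,include_stage1_pred,include_pred_derivative,include_spherical
#'   Flags overriding the stage defaults.
#' @return An `fmg_recipe`.
#' @export
feature_recipe <- function(stage,
                           include_raw = TRUE,
                           include_derivative = TRUE,
                           include_stage1_pred = stage == 2,
                           include_pred_derivative = stage == 2,
                           include_spherical = stage == 2) {
  if (!stage %in% 1:2) stop_config("stage must be 1 or 2")
  structure(
    list(stage = stage,
         include_raw = include_raw,
         include_derivative = include_derivative,
         include_stage1_pred = include_stage1_pred,
         include_pred_derivative = include_pred_derivative,
         include_spherical = include_spherical),
    class = "fmg_recipe"
  )
}

#' Assemble the feature matrix for one stage
#'
#' Blocks are concatenated in the fixed order
#' `raw | d(raw) | pred | d(pred) | spherical(pred)`; column names record
#' block identity. Derivatives are computed within trials when `trial_id`
#' is given.
#'
#' @param recipe An [feature_recipe()].
#' @param fmg Samples x channels normalized FMG matrix.
#' @param stage1_pred Samples x outputs stage-1 prediction matrix
#'   (required for stage-2 recipes).
#' @param trial_id Optional per-sample trial labels for the derivative.
#' @return Samples x features matrix.
#' @export
assemble_features <- function(recipe, fmg, stage1_pred = NULL, trial_id = NULL) {
  fmg <- as_matrix(fmg)
  blocks <- list()
  if (recipe$include_raw) blocks$raw <- fmg
  if (recipe$include_derivative) blocks$draw <- derivative(fmg, trial_id)
  if (recipe$include_stage1_pred || recipe$include_pred_derivative ||
      recipe$include_spherical) {
    if (is.null(stage1_pred)) {
      stop_input("stage-2 recipe requires stage-1 predictions")
    }
    p <- as_matrix(stage1_pred)
    if (nrow(p) != nrow(fmg)) {
      stop_input("stage-1 predictions and FMG disagree on row count")
    }
    if (is.null(colnames(p))) colnames(p) <- paste0("pred", seq_len(ncol(p)))
    if (recipe$include_stage1_pred) blocks$pred <- p
    if (recipe$include_pred_derivative) blocks$dpred <- derivative(p, trial_id)
    if (recipe$include_spherical) blocks$sph <- spherical_transform(p)
  }
  do.call(cbind, blocks)
}
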