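#' Two-way fixed-effects ANOVA with interaction
#'
#' Tests the effects of two crossed factors (here typically band
#' combination and stage-1 algorithm) on a response (per-subject mean
#' R-squared), via the standard fixed-effects two-way ANOVA with
#' interaction fitted by [stats::aov()]. Every factor-level cell must be
#' nonempty; a balanced design (equal replicates per cell) is expected.
#'
#' @param values Numeric response, one observation per row.
#' @param factor_a,factor_b Level labels, same length as `values`.
#' @return A tibble with one row per effect (`factor_a`, `factor_b`,
#'   `interaction`, `residuals`): `df`, `sumsq`, `meansq`, `F`, `p`.
#'   When the response is constant, F and p are `NaN` and total SS is 0.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  if (length(values) != length(factor_a) || length(values) != length(factor_b)) {
    stop_input("values and factor labels must have equal length")
  }
  a <- factor(factor_a); b <- factor(factor_b)
  if (any(table(a, b) == 0L)) stop_input("every factor-level cell must be nonempty")
  df <- data.frame(y = values, a = a, b = b)
  fit <- stats::aov(y ~ a * b, data = df)
  tab <- summary(fit)[[1]]
  if (sum((values - mean(values))^2) < 1e-12 * max(1, mean(values)^2)) {
    tab$`F value`[] <- NaN
    tab$`Pr(>F)`[] <- NaN
  }
  terms <- trimws(rownames(tab))
  name_map <- c("a" = "factor_a", "b" = "factor_b", "a:b" = "interaction",
                "Residuals" = "residuals")
  tibble::tibble(
    effect = unname(name_map[terms]),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    F = tab$`F value`,
    p = tab$`Pr(>F)`
  )
}

#' Tukey HSD pairwise comparisons from cell means
#'
#' Studentized-range post-hoc test over all level pairs:
#' `q = |m_i - m_j| / sqrt(mse / n)` referred to the studentized range
#' distribution with `k` means and the residual degrees of freedom.
#' Intended to follow a significant ANOVA factor effect.
#'
#' @param cell_means Named numeric vector of level means.
#' @param mse Residual mean square from the ANOVA.
#' @param n_per_level Observations per level (balanced; >= 2).
#' @param df_resid Residual degrees of freedom.
#' @param alpha Family-wise significance level.
#' @return A tibble with one row per level pair: `level1`, `level2`,
#'   `diff`, `q`, `p`, `significant`.
#' @export
tukey_hsd <- function(cell_means, mse, n_per_level, df_resid, alpha = 0.05) {
  k <- length(cell_means)
  if (k < 2L) stop_input("need at least 2 levels")
  if (n_per_level < 2L) stop_input("need at least 2 observations per level")
  if (is.null(names(cell_means))) names(cell_means) <- paste0("L", seq_len(k))
  pairs <- utils::combn(names(cell_means), 2, simplify = FALSE)
  se <- sqrt(mse / n_per_level)
  rows <- lapply(pairs, function(pr) {
    d <- cell_means[[pr[1]]] - cell_means[[pr[2]]]
    q <- abs(d) / se
    p <- stats::ptukey(q, nmeans = k, df = df_resid, lower.tail = FALSE)
    tibble::tibble(level1 = pr[1], level2 = pr[2], diff = d, q = q, p = p,
                   significant = p < alpha)
  })
  do.call(rbind, rows)
}

#' Tukey HSD for one factor of a fitted two-way design
#'
#' Convenience wrapper: computes the factor's level means, pulls the
#' residual mean square and degrees of freedom from [two_way_anova()],
#' and calls [tukey_hsd()].
#'
#' @inheritParams two_way_anova
#' @param which `"a"` or `"b"`: which factor to compare.
#' @param alpha Family-wise significance level.
#' @return The [tukey_hsd()] table.
#' @export
tukey_hsd_factor <- function(values, factor_a, factor_b, which = c("a", "b"),
                             alpha = 0.05) {
  which <- match.arg(which)
  an <- two_way_anova(values, factor_a, factor_b)
  resid <- an[an$effect == "residuals", ]
  f <- factor(if (which == "a") factor_a else factor_b)
  means <- tapply(values, f, mean)
  n_per <- length(values) / nlevels(f)
  tukey_hsd(as.numeric(means) |> stats::setNames(levels(f)),
            mse = resid$meansq, n_per_level = n_per,
            df_resid = resid$df, alpha = alpha)
}
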