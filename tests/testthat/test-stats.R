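test_that("two-way ANOVA reproduces a hand-partitioned 2x2 design", {
  # 2 x 2 with 3 replicates; sums of squares computed by hand from cell means
  a <- rep(c("a1", "a2"), each = 6)
  b <- rep(rep(c("b1", "b2"), each = 3), 2)
  y <- c(1, 2, 3, 4, 5, 6, 2, 3, 4, 7, 8, 9)
  res <- two_way_anova(y, a, b)
  gm <- mean(y)
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, paste(a, b), mean)
  ss_a <- 6 * sum((m_a - gm)^2)
  ss_b <- 6 * sum((m_b - gm)^2)
  cell <- tapply(y, paste(a, b), mean)[paste(a, b)]
  ss_resid <- sum((y - cell)^2)
  ss_ab <- sum((y - gm)^2) - ss_a - ss_b - ss_resid
  expect_equal(res$sumsq[res$effect == "factor_a"], ss_a)
  expect_equal(res$sumsq[res$effect == "factor_b"], ss_b)
  expect_equal(res$sumsq[res$effect == "interaction"], ss_ab)
  expect_equal(res$sumsq[res$effect == "residuals"], ss_resid)
  expect_equal(res$df, c(1, 1, 1, 8))
  mse <- ss_resid / 8
  expect_equal(res$F[res$effect == "factor_a"], (ss_a / 1) / mse)
})

test_that("factor degrees of freedom equal levels minus one (15 combos -> 14)", {
  set.seed(51)
  combos <- vapply(enumerate_combinations(), format, character(1))
  df <- expand.grid(combo = combos, algo = c("grnn", "svr", "rf"),
                    subject = paste0("S", 1:3))
  y <- rnorm(nrow(df))
  res <- two_way_anova(y, df$combo, df$algo)
  expect_equal(res$df[res$effect == "factor_a"], 14)
  expect_equal(res$df[res$effect == "factor_b"], 2)
})

test_that("constant response gives zero total SS and flagged statistics", {
  a <- rep(c("x", "y"), each = 4); b <- rep(c("u", "v"), 4)
  res <- two_way_anova(rep(1, 8), a, b)
  expect_equal(sum(res$sumsq), 0, tolerance = 1e-12)
  expect_false(any(is.finite(res$F[res$effect != "residuals"]) &
                     res$F[res$effect != "residuals"] > 0))
})

test_that("empty cells are labeled input errors", {
  expect_error(two_way_anova(1:3, c("a", "a", "b"), c("u", "v", "u")),
               class = "fmg_input_error")
})

test_that("type-I error of the factor tests is calibrated under the null", {
  # all cells drawn from one distribution; 15 x 3 design, 9 replicates
  set.seed(52)
  combos <- vapply(enumerate_combinations(), format, character(1))
  grid <- expand.grid(combo = combos, algo = c("g", "s", "r"),
                      subject = 1:9)
  n_sim <- 400
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    y <- rnorm(nrow(grid))
    res <- two_way_anova(y, grid$combo, grid$algo)
    rej[i] <- res$p[res$effect == "factor_a"] < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("identical level means give Tukey p of 1", {
  tk <- tukey_hsd(c(a = 1, b = 1, c = 2), mse = 0.5, n_per_level = 5,
                  df_resid = 12)
  expect_equal(tk$p[tk$level1 == "a" & tk$level2 == "b"], 1)
})

test_that("tukey_hsd agrees with stats::TukeyHSD on a one-way design", {
  set.seed(53)
  g <- rep(c("a", "b", "c"), each = 10)
  y <- rnorm(30) + c(a = 0, b = 0.5, c = 2)[g]
  fit <- stats::aov(y ~ g)
  ref <- stats::TukeyHSD(fit)$g
  ms <- summary(fit)[[1]]$`Mean Sq`[2]
  tk <- tukey_hsd(tapply(y, g, mean), mse = ms, n_per_level = 10,
                  df_resid = 27)
  # match pairs by name
  for (i in seq_len(nrow(tk))) {
    key <- paste0(tk$level2[i], "-", tk$level1[i])
    expect_equal(unname(tk$p[i]), unname(ref[key, "p adj"]), tolerance = 1e-8)
  }
})

test_that("tukey significance calls agree with a permutation oracle", {
  # 3-level toy data with one clearly separated level
  set.seed(54)
  g <- rep(c("a", "b", "c"), each = 10)
  mu <- c(a = 0, b = 0.1, c = 2)
  y <- rnorm(30, mu[g], 1)
  fit <- stats::aov(y ~ g)
  ms <- summary(fit)[[1]]$`Mean Sq`[2]
  tk <- tukey_hsd(tapply(y, g, mean), mse = ms, n_per_level = 10, df_resid = 27)
  # permutation null of the maximum studentized pairwise statistic
  # (vectorized: columns of Yp are permuted datasets)
  n_perm <- 1e5
  obs_q <- tk$q
  set.seed(99)
  Yp <- vapply(seq_len(n_perm), function(i) sample(y), numeric(30))
  G <- t(sapply(c("a", "b", "c"), function(lv) as.numeric(g == lv)))
  M <- (G %*% Yp) / 10                       # 3 x n_perm group means
  ss_between <- 10 * colSums((M - mean(y))^2) # column means all equal mean(y)
  # total SS is permutation-invariant
  ss_total <- sum((y - mean(y))^2)
  msw <- (ss_total - ss_between) / 27
  rng <- pmax(abs(M[1, ] - M[2, ]), abs(M[1, ] - M[3, ]), abs(M[2, ] - M[3, ]))
  perm_max <- rng / sqrt(msw / 10)
  p_perm <- vapply(obs_q, function(q) mean(perm_max >= q), numeric(1))
  # agreement of p-values within Monte-Carlo error, and same calls at 0.05
  expect_equal(p_perm < 0.05, tk$significant)
  expect_true(all(abs(p_perm - tk$p) < 0.03))
})

test_that("degenerate Tukey inputs are labeled errors", {
  expect_error(tukey_hsd(c(a = 1), 1, 5, 10), class = "fmg_input_error")
  expect_error(tukey_hsd(c(a = 1, b = 2), 1, 1, 10), class = "fmg_input_error")
})
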