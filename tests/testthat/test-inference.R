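test_that("paired t matches hand computation and symmetries", {
  # differences (1, 2, 3): t = 2 / (1 / sqrt(3)), df = 2
  res <- paired_t(c(1, 2, 3), c(0, 0, 0), bf = FALSE)
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$cohens_d, 2)

  # identical vectors
  same <- paired_t(c(1, 2, 3), c(1, 2, 3), bf = FALSE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$cohens_d, 0)

  # sign flip negates t, p unchanged
  x <- c(0.1, 0.5, 0.3, 0.9, 0.2)
  y <- c(0.2, 0.3, 0.5, 0.4, 0.4)
  a <- paired_t(x, y, bf = FALSE)
  b <- paired_t(y, x, bf = FALSE)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)

  expect_error(paired_t(c(1, 2), c(0, 1)), "zero variance")
})

test_that("JZS Bayes factor matches dense-grid quadrature", {
  cases <- expand.grid(t = c(0.5, 2, 4.87), n = c(12, 24), r = c(0.707, 1))
  for (i in seq_len(nrow(cases))) {
    got <- jzs_bf_paired(cases$t[i], cases$n[i], cases$r[i])
    want <- oracle_jzs(cases$t[i], cases$n[i], cases$r[i])
    expect_equal(got, want, tolerance = 1e-4)
  }
  # null-favouring at t = 0; monotone in |t|
  expect_lt(jzs_bf_paired(0, 24), 1)
  bfs <- vapply(seq(0, 6, by = 0.5), jzs_bf_paired, numeric(1), n = 24)
  expect_false(is.unsorted(bfs, strictly = TRUE))
})

test_that("one-way RM ANOVA matches the sums-of-squares oracle", {
  set.seed(314)
  n <- 4; k <- 3
  Y <- matrix(rnorm(n * k, mean = rep(c(0, 0.4, 1), each = n)), n, k)
  d <- tibble::tibble(
    pid = rep(seq_len(n), k),
    cond = rep(c("A", "B", "C"), each = n),
    y = as.vector(Y)
  )
  got <- rm_anova_oneway(d, y, pid, cond)
  want <- oracle_rm_oneway(Y)
  expect_equal(got$effects$statistic, want$f, tolerance = 1e-10)
  expect_equal(got$effects$df1, want$df1)
  expect_equal(got$effects$df2, want$df2)

  # per-participant constant shifts leave F unchanged
  d2 <- dplyr::mutate(d, y = y + pid * 7)
  expect_equal(rm_anova_oneway(d2, y, pid, cond)$effects$statistic,
               want$f, tolerance = 1e-10)

  # identical conditions within participant: F = 0
  d3 <- dplyr::mutate(d, y = pid * 1.5)
  expect_equal(rm_anova_oneway(d3, y, pid, cond)$effects$statistic, 0)

  # two conditions: F equals the paired t squared
  d4 <- dplyr::filter(d, cond != "C")
  w <- tidyr::pivot_wider(d4, names_from = cond, values_from = y)
  expect_equal(
    rm_anova_oneway(d4, y, pid, cond)$effects$statistic,
    paired_t(w$A, w$B, bf = FALSE)$statistic^2,
    tolerance = 1e-10
  )

  expect_error(rm_anova_oneway(d[-1, ], y, pid, cond), "complete")
})

test_that("3x3 RM ANOVA matches the sums-of-squares oracle", {
  set.seed(2718)
  n <- 3
  Y <- array(rnorm(n * 9), dim = c(n, 3, 3))
  Y <- Y + rep(c(0, 0.5, 1.2), each = n) # A main effect
  d <- tibble::tibble(
    pid = rep(seq_len(n), 9),
    A = rep(rep(c("a1", "a2", "a3"), each = n), 3),
    B = rep(c("b1", "b2", "b3"), each = 3 * n),
    y = as.vector(Y)
  )
  got <- rm_anova_3x3(d, y, pid, A, B)
  want <- oracle_rm_3x3(Y)
  eff <- got$effects
  expect_equal(eff$statistic[eff$effect == "A"], want$f_a, tolerance = 1e-10)
  expect_equal(eff$statistic[eff$effect == "B"], want$f_b, tolerance = 1e-10)
  expect_equal(eff$statistic[eff$effect == "A:B"], want$f_ab,
               tolerance = 1e-10)
  expect_equal(eff$df1, c(2, 2, 4))
  expect_equal(eff$df2, c(2 * (n - 1), 2 * (n - 1), 4 * (n - 1)))

  # swapping the factor roles permutes the main-effect F values
  swapped <- rm_anova_3x3(d, y, pid, B, A)
  expect_equal(
    swapped$effects$statistic[swapped$effects$effect == "A"],
    want$f_b, tolerance = 1e-10
  )
  expect_equal(
    swapped$effects$statistic[swapped$effects$effect == "B"],
    want$f_a, tolerance = 1e-10
  )

  # additive construction with no noise: interaction F ~ 0
  d_add <- dplyr::mutate(
    d, y = as.numeric(factor(A)) + 0.3 * as.numeric(factor(B)) + pid
  )
  got_add <- rm_anova_3x3(d_add, y, pid, A, B)
  f_int <- got_add$effects$statistic[got_add$effects$effect == "A:B"]
  expect_lt(abs(f_int), 1e-10)
})

test_that("Tukey adjusted p matches the studentized-range oracle", {
  means <- c(M = 0.22, O = 0.30, N1 = 0.58)
  tk <- tukey_ranges(means, error_ms = 0.005, error_df = 46, n_per_mean = 24)
  for (i in seq_len(nrow(tk$table))) {
    expect_equal(
      tk$table$p_adj[i],
      oracle_tukey_p(tk$table$q[i], k = 3, df = 46),
      tolerance = 1e-6
    )
  }
  expect_equal(tk$chain, "N1 > O > M")

  # equal means: adjusted p = 1
  tk0 <- tukey_ranges(c(a = 0.4, b = 0.4), 0.01, 10, 8)
  expect_equal(tk0$table$p_adj, 1)

  # p non-increasing in |difference| at fixed error
  diffs <- seq(0.02, 0.4, by = 0.02)
  ps <- vapply(diffs, function(dd) {
    tukey_ranges(c(a = 0, b = dd), 0.02, 30, 10)$table$p_adj
  }, numeric(1))
  expect_false(is.unsorted(rev(ps)))

  expect_error(tukey_ranges(c(a = 1, b = 2), 0.1, 0, 5), "error_df")
})

test_that("paired test holds its nominal type-I error under the null", {
  set.seed(11)
  reps <- 500
  pvals <- replicate(reps, {
    x <- rnorm(24); y <- rnorm(24)
    paired_t(x, y, bf = FALSE)$p_value
  })
  rate <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 3 * se + 1e-9)
})
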