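test_that("log-logistic values and limits are exact", {
  expect_equal(loglogistic(0, a = 0.2, b = 0, c = 1), 0.6)
  expect_equal(loglogistic(2, a = 0.1, b = 2, c = 1), 0.55)
  expect_equal(loglogistic(1e6, a = 0.3, b = 1, c = 2), 1)
  expect_equal(loglogistic(-1e6, a = 0.3, b = 1, c = 2), 0.3)
  # bounded between the floor a and 1 over a parameter grid
  grid <- expand.grid(a = c(0, 0.3, 0.9), b = c(-2, 0, 4), c = c(0, 1, 3),
                      x = 0:5)
  p_no <- with(grid, mapply(loglogistic, x, a, b, c))
  expect_true(all(p_no >= grid$a - 1e-12 & p_no <= 1 + 1e-12))
  # non-decreasing in x whenever the slope is positive
  for (aa in c(0, 0.3)) {
    expect_false(is.unsorted(loglogistic(0:5, aa, 1.5, 1.2)))
  }
})

test_that("noiseless data are recovered exactly and deterministically", {
  x <- 0:5
  truth <- c(a = 0.2, b = 1.5, c = 1.2)
  tab <- tibble::tibble(
    participant_id = "P01", experiment = 1L, scheme = "from_mean",
    category = c("M", "O", "N1", "N2", "N3", "N4"), x = x,
    n_trials = c(120L, 240L, 40L, 30L, 25L, 20L),
    n_no = 0L
  )
  tab$p_no <- loglogistic(x, truth["a"], truth["b"], truth["c"])
  fit <- fit_psychometric(tab)
  expect_true(fit$converged)
  expect_equal(fit$a, unname(truth["a"]), tolerance = 1e-4)
  expect_equal(fit$b, unname(truth["b"]), tolerance = 1e-4)
  expect_equal(fit$c, unname(truth["c"]), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_identical(fit_psychometric(tab), fit)

  # constant p(No): slope collapses to the boundary and is flagged
  flat <- dplyr::mutate(tab, p_no = 0.4)
  expect_true(fit_psychometric(flat)$degenerate)

  expect_error(fit_psychometric(tab[1:3, ]), "fewer than")
})

test_that("BIC formulas match hand evaluation and scale correctly", {
  expect_equal(bic_gaussian(0.005, 5), 5 * log(0.001) + 3 * log(5))
  expect_equal(bic_gaussian(0.005, 5), -29.71, tolerance = 0.005)
  # doubling RSS at fixed n adds n * ln 2
  expect_equal(
    bic_gaussian(0.02, 6) - bic_gaussian(0.01, 6), 6 * log(2)
  )
  expect_true(bic_gaussian(0.004, 5) < bic_gaussian(0.005, 5))
  expect_message(out <- bic_gaussian(0, 5), "-Inf")
  expect_equal(out, -Inf)

  # binomial variant: better fit, lower BIC
  x <- 0:5; n_tr <- rep(50L, 6)
  p <- loglogistic(x, 0.2, 1.5, 1.2)
  n_no <- round(p * 50)
  good <- bic_binomial(x, n_no, n_tr, 0.2, 1.5, 1.2)
  bad <- bic_binomial(x, n_no, n_tr, 0.05, 4, 0.8)
  expect_lt(good, bad)
})

test_that("scheme comparison pairs fits and reports direction", {
  fits <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:6), 2),
    scheme = rep(c("from_mean", "from_old"), each = 6),
    bic = c(rnorm(6, -20), rnorm(6, -20)),
    r_squared = runif(12, 0.9, 1)
  )
  fits_same <- fits
  fits_same$bic <- rep(fits$bic[1:6], 2)
  fits_same$r_squared <- rep(fits$r_squared[1:6], 2)
  same <- compare_schemes(fits_same, bf = FALSE)
  expect_equal(same$statistic, 0)
  expect_equal(same$mean_bic_from_mean, same$mean_bic_from_old)

  shifted <- fits
  shifted$bic[shifted$scheme == "from_old"] <-
    shifted$bic[shifted$scheme == "from_mean"] -
    seq(1.5, 2.5, length.out = 6)
  cmp <- compare_schemes(shifted, bf = FALSE)
  expect_gt(cmp$statistic, 0) # positive t: from_old fits better
  expect_equal(cmp$mean_bic_from_mean - cmp$mean_bic_from_old, 2)

  expect_error(
    compare_schemes(fits[fits$scheme == "from_mean", ], bf = FALSE),
    "both schemes"
  )
})

test_that("scheme comparison recovers each generating rule's direction", {
  # similarity-generated data: from_old (pooled, the default) fits better
  sim_dat <- simulate_experiment(
    1, n_participants = 12,
    observer = observer_similarity(lambda = 0), seed = 15
  )
  cond <- dplyr::bind_rows(
    condition_table(sim_dat, "from_mean"),
    condition_table(sim_dat, "from_old")
  )
  cmp_sim <- compare_schemes(fit_psychometric(cond), bf = FALSE)
  expect_gt(cmp_sim$statistic, 0)
  expect_lt(cmp_sim$mean_bic_from_old, cmp_sim$mean_bic_from_mean)

  # averaging-generated data: with M and N1 unpooled the from_mean fit is
  # not worse on average (pooling would smooth away the M/N1 contrast)
  avg_dat <- simulate_experiment(
    1, n_participants = 12,
    observer = observer_averaging(lambda = 0), seed = 15
  )
  cond_avg <- dplyr::bind_rows(
    condition_table(avg_dat, "from_mean"),
    condition_table(avg_dat, "from_old")
  )
  cmp_avg <- compare_schemes(
    fit_psychometric(cond_avg, pool_m_n1 = FALSE), bf = FALSE
  )
  expect_lte(cmp_avg$mean_bic_from_mean, cmp_avg$mean_bic_from_old)
})
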