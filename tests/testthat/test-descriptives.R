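test_that("probe classification distances are exact", {
  expect_equal(classify_probe(1, 3, 4), tibble::tibble(
    dist_from_mean = 2, dist_from_old = 1
  ))
  expect_equal(classify_probe(1, 3, 2)$dist_from_mean, 0)
  expect_equal(classify_probe(1, 3, 2)$dist_from_old, 1)
  expect_equal(classify_probe(1, 3, 7), tibble::tibble(
    dist_from_mean = 5, dist_from_old = 4
  ))
  expect_error(classify_probe(1, 4, 2), "two ordinal steps")
})

test_that("scheme distances are mutually consistent on generated designs", {
  expt <- dplyr::filter(generate_session(1, "P01", 31), !practice_flag)
  nn <- expt$relevant_probe_class == "N"
  expect_true(all(
    expt$relevant_dist_from_mean[nn] == expt$relevant_dist_from_old[nn] + 1
  ))
  mm <- expt$relevant_probe_class == "M"
  expect_true(all(expt$relevant_dist_from_mean[mm] == 0))
  expect_true(all(expt$relevant_dist_from_old[mm] == 1))
  o <- expt$relevant_probe_class == "O"
  expect_true(all(expt$relevant_dist_from_mean[o] == 1))
  expect_true(all(expt$relevant_dist_from_old[o] == 0))
})

test_that("condition tables are exact ratios under both schemes", {
  rows <- make_manual_trials(tibble::tibble(
    relevant_probe_class = rep(c("M", "O", "N"), c(10, 4, 6)),
    relevant_dist_from_mean = rep(c(0L, 1L, 2L), c(10, 4, 6)),
    relevant_dist_from_old = rep(c(1L, 0L, 1L), c(10, 4, 6)),
    relevant_side = rep(c("n/a", "n/a", "below"), c(10, 4, 6)),
    response = c(rep("No", 2), rep("Yes", 8), rep("Yes", 4),
                 rep("No", 3), rep("Yes", 3))
  ))
  tab <- condition_table(rows, "from_mean")
  expect_equal(tab$p_no[tab$category == "M"], 0.2)
  expect_equal(tab$x[tab$category == "M"], 0)
  expect_equal(tab$x[tab$category == "O"], 1)
  expect_equal(tab$x[tab$category == "N1"], 2)
  expect_equal(sum(tab$n_trials), 20)

  old <- condition_table(rows, "from_old")
  expect_equal(old$x[old$category == "O"], 0)
  expect_equal(old$x[old$category == "M"], 1)
  expect_equal(old$x[old$category == "N1"], 1)

  all_yes <- dplyr::mutate(rows, response = "Yes")
  expect_true(all(condition_table(all_yes, "from_mean")$p_no == 0))
})

test_that("category proportions track generating probabilities", {
  obs <- observer_averaging(lambda = 0)
  dat <- simulate_experiment(1, n_participants = 1, observer = obs, seed = 6)
  tab <- condition_table(dat, "from_mean")
  truth <- loglogistic(tab$x, 0.2034483, 3.8528039, 1.8718023)
  se <- sqrt(truth * (1 - truth) / tab$n_trials)
  expect_true(all(abs(tab$p_no - truth) < pmax(4 * se, 0.02)))
})

test_that("the chance-performance exclusion rule applies as configured", {
  mk <- function(p_no_maxn) {
    make_manual_trials(tibble::tibble(
      relevant_probe_class = rep(c("M", "O", "N", "N"), each = 20),
      relevant_dist_from_mean = rep(c(0L, 1L, 2L, 5L), each = 20),
      relevant_dist_from_old = rep(c(1L, 0L, 1L, 4L), each = 20),
      relevant_side = rep(c("n/a", "n/a", "below", "above"), each = 20),
      response = c(
        rep("Yes", 60),
        rep(c("No", "Yes"), c(round(20 * p_no_maxn), 20 - round(20 * p_no_maxn)))
      )
    ))
  }
  expect_true(exclude_participants(mk(0.45))$log$excluded)
  expect_false(exclude_participants(mk(0.55))$log$excluded)
  # boundary: at exactly chance, default excludes, strict variant retains
  expect_true(exclude_participants(mk(0.50))$log$excluded)
  expect_false(exclude_participants(mk(0.50), strict = TRUE)$log$excluded)
  # retained table drops the excluded participant's trials
  expect_equal(nrow(exclude_participants(mk(0.45))$retained), 0)
})

test_that("similarity point prediction follows the product rule", {
  # direct probability forms
  expect_equal(predict_similarity_no(1, 1), 1)
  expect_equal(predict_similarity_no(0.6, 0.5), 0.3)
  expect_equal(predict_similarity_yes(0.4, 0.4), 0.64)

  # complement identity on a probability grid
  p <- seq(0, 1, by = 0.05)
  grid <- expand.grid(a = p, b = p)
  expect_equal(
    predict_similarity_yes(1 - grid$a, 1 - grid$b),
    1 - predict_similarity_no(grid$a, grid$b)
  )

  # estimated from trials, side-specific policy
  rows <- make_manual_trials(tibble::tibble(
    relevant_probe_class = rep(c("N", "N", "M"), each = 10),
    relevant_dist_from_mean = rep(c(2L, 2L, 0L), each = 10),
    relevant_dist_from_old = rep(c(1L, 1L, 1L), each = 10),
    relevant_side = rep(c("below", "above", "n/a"), each = 10),
    response = c(rep(c("No", "Yes"), c(6, 4)), rep(c("No", "Yes"), c(5, 5)),
                 rep(c("No", "Yes"), c(3, 7)))
  ))
  pred <- similarity_prediction(rows)
  expect_equal(pred$policy_used, "side")
  expect_equal(pred$p_no_n1a, 0.6)
  expect_equal(pred$p_no_n1b, 0.5)
  expect_equal(pred$p_no_m_pred, 0.3)
  expect_equal(pred$p_no_m_obs, 0.3)
  expect_equal(pred$p_yes_m_pred, 0.7)

  # starving one side falls back to the pooled square
  pooled <- similarity_prediction(rows, n_min = 11)
  expect_equal(pooled$policy_used, "pooled")
  expect_equal(pooled$p_no_m_pred, 0.55^2)
  expect_identical(
    similarity_prediction(rows, n1_policy = "pooled")$p_no_m_pred, 0.55^2
  )
})
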