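test_that("single-dimension sessions have the designed trial counts", {
  trials <- generate_session(1, "P01", seed = 11)
  expect_equal(nrow(trials), 500)
  expect_equal(sum(trials$practice_flag), 20)
  expt <- dplyr::filter(trials, !practice_flag)
  counts <- table(expt$relevant_probe_class)
  expect_equal(unname(counts[c("O", "M", "N")]), c(240, 120, 120),
               ignore_attr = TRUE)
  expect_equal(unname(table(expt$block)), rep(96L, 5), ignore_attr = TRUE)
  expect_equal(unname(table(expt$family)), c(240L, 240L), ignore_attr = TRUE)
  expect_true(all(is.na(expt$irrelevant_probe_class)))
  expect_equal(unique(expt$relevant_dimension), "orientation")
  expect_equal(unique(generate_session(2, "P01", 1)$relevant_dimension[1]),
               "color")
})

test_that("factorial sessions have the 3x3 cell counts", {
  for (e in 3:4) {
    expt <- dplyr::filter(generate_session(e, "P01", seed = 5), !practice_flag)
    expect_equal(nrow(expt), 480)
    cells <- dplyr::count(
      expt, relevant_probe_class, irrelevant_probe_class
    )
    expect_equal(nrow(cells), 9)
    expect_equal(
      cells$n[cells$relevant_probe_class == "O"], rep(80L, 3)
    )
    expect_equal(
      cells$n[cells$relevant_probe_class != "O"], rep(40L, 6)
    )
  }
  expect_error(generate_session(5, "P01", 1), "unknown experiment")
})

test_that("sessions and responses are bit-reproducible under a seed", {
  a <- generate_session(3, "P07", seed = 99)
  b <- generate_session(3, "P07", seed = 99)
  expect_identical(a, b)
  obs <- observer_averaging()
  ra <- simulate_responses(a, obs, seed = 99)
  rb <- simulate_responses(b, obs, seed = 99)
  expect_identical(ra, rb)
  # design is invariant to the observer model (separate sub-streams)
  rc <- simulate_responses(a, observer_similarity(), seed = 99)
  expect_identical(
    dplyr::select(ra, -p_no_true, -response),
    dplyr::select(rc, -p_no_true, -response)
  )
})

test_that("observer response probabilities match hand calculations", {
  t_m <- make_manual_trials(tibble::tibble(
    relevant_probe_class = "M", rel_old_lower = 1L, rel_old_upper = 3L,
    rel_probe_index = 2L, relevant_dist_from_mean = 0L,
    relevant_dist_from_old = 1L, relevant_side = "n/a"
  ))
  # similarity, M probe, g(1) = 0.6, g(d >= 2) = 0: (1 - 0.6)^2
  sim <- observer_similarity(kernel = c(0.9, 0.6), lambda = 0)
  r <- simulate_responses(t_m, sim, seed = 1)
  expect_equal(r$p_no_true, 0.16)

  # averaging, M probe (x = 0), a = 0.2, b = 0, c = 1: 0.2 + 0.8/2
  avg <- observer_averaging(a = 0.2, b = 0, c = 1, lambda = 0)
  expect_equal(simulate_responses(t_m, avg, seed = 1)$p_no_true, 0.6)

  # similarity, O probe, g(0) = 0.95, g(2) = 0.1: 0.05 * 0.9
  t_o <- make_manual_trials(tibble::tibble(
    relevant_probe_class = "O", rel_old_lower = 1L, rel_old_upper = 3L,
    rel_probe_index = 1L, relevant_dist_from_mean = 1L,
    relevant_dist_from_old = 0L, relevant_side = "n/a"
  ))
  sim2 <- observer_similarity(kernel = c(0.95, 0.5, 0.1), lambda = 0)
  expect_equal(simulate_responses(t_o, sim2, seed = 1)$p_no_true, 0.045)
})

test_that("observer p(No) is monotone in the scheme-relevant distance", {
  trials <- dplyr::filter(generate_session(1, "P01", 2), !practice_flag)
  avg <- simulate_responses(trials, observer_averaging(lambda = 0), seed = 2)
  by_mean <- avg |>
    dplyr::group_by(relevant_dist_from_mean) |>
    dplyr::summarise(p = mean(p_no_true)) |>
    dplyr::arrange(relevant_dist_from_mean)
  expect_false(is.unsorted(by_mean$p))

  sim <- simulate_responses(trials, observer_similarity(lambda = 0), seed = 2)
  by_old <- sim |>
    dplyr::group_by(relevant_dist_from_old) |>
    dplyr::summarise(p = mean(p_no_true)) |>
    dplyr::arrange(relevant_dist_from_old)
  expect_false(is.unsorted(by_old$p))

  # invalid kernels are rejected
  expect_error(observer_similarity(kernel = c(0.2, 0.6)), "non-increasing")
  expect_error(observer_similarity(kernel = c(1.2, 0.5)))
})

test_that("layouts satisfy the display constraints", {
  trial <- generate_session(3, "P01", seed = 8)[25, ]
  lay <- generate_layout(trial, seed = 8)
  expect_equal(nrow(lay), 64)
  expect_true(all((lay$x - 500)^2 + (lay$y - 400)^2 > 40^2))
  expect_true(all(lay$x >= 0 & lay$x <= 1000 & lay$y >= 0 & lay$y <= 800))
  expect_equal(unname(table(lay$relevant_level)), c(32L, 32L),
               ignore_attr = TRUE)
  # balanced crossing: 16 bars per old-orientation x old-colour combination
  combo <- table(lay$relevant_level, lay$irrelevant_level)
  expect_equal(unname(as.vector(combo)), rep(16L, 4))
  expect_identical(lay, generate_layout(trial, seed = 8))

  lay1 <- generate_layout(generate_session(1, "P01", 1)[30, ], seed = 1)
  expect_true(all(is.na(lay1$irrelevant_level)))
})
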