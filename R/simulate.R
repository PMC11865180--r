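#' Generate one participant's trial sequence
#'
#' Builds the full within-session design for one of the four experiments:
#'
#' * Experiments 1 (judge orientation) and 2 (judge colour): 480
#'   experimental trials — 240 old (O), 120 mean (M) and 120 new (N) probes
#'   on the relevant dimension — preceded by 20 flagged practice trials, in
#'   five blocks of 96; the series family (tilt direction, or hue) is
#'   balanced half/half over trials.
#' * Experiments 3 (judge colour, orientation varies) and 4 (judge
#'   orientation, colour varies): the 3 x 3 factorial of relevant x
#'   irrelevant probe class, with 80 trials per cell when the relevant probe
#'   is O and 40 when it is M or N (480 in total), plus 20 practice trials.
#'
#' On every trial the old pair is drawn afresh (two series levels two steps
#' apart, lower index uniform on 1-5) and the probe is placed per
#' [assign_probe()]. The design stream is seeded independently of the
#' response stream, so the same seed yields the same trial list under any
#' observer.
#'
#' @param experiment 1, 2, 3 or 4.
#' @param participant_id Identifier string.
#' @param seed Integer root seed for the session.
#' @return A tibble with one row per trial (practice included, flagged):
#'   identifiers, block and trial index, relevant- and (for experiments 3-4)
#'   irrelevant-dimension series indices, probe classes, ordinal distances
#'   and sides.
#' @export
#' @examples
#' trials <- generate_session(1, "P01", seed = 1)
#' dplyr::count(dplyr::filter(trials, !practice_flag), relevant_probe_class)
generate_session <- function(experiment, participant_id = "P01", seed = 1) {
  if (!experiment %in% 1:4) {
    stop("unknown experiment id: ", experiment, call. = FALSE)
  }
  rel_dim <- if (experiment %in% c(1, 4)) "orientation" else "color"
  irr_dim <- switch(as.character(experiment),
    "3" = "orientation", "4" = "color", NA_character_
  )

  cls <- function(n_o, n_m, n_n) rep(c("O", "M", "N"), c(n_o, n_m, n_n))
  if (experiment %in% 1:2) {
    rel_class <- cls(240, 120, 120)
    irr_class <- rep(NA_character_, 480)
    rel_prac <- cls(10, 5, 5)
    irr_prac <- rep(NA_character_, 20)
  } else {
    cells <- tidyr::expand_grid(
      rel = c("O", "M", "N"), irr = c("M", "N", "O")
    )
    cells$n <- ifelse(cells$rel == "O", 80L, 40L)
    rel_class <- rep(cells$rel, cells$n)
    irr_class <- rep(cells$irr, cells$n)
    rel_prac <- cls(10, 5, 5)
    irr_prac <- rep(c("M", "N", "O"), length.out = 20)
  }

  build <- with_stream(seed, paste0("design/", experiment, "/", participant_id), {
    n_exp <- length(rel_class)
    ord <- sample.int(n_exp)
    rel_class <- rel_class[ord]
    irr_class <- irr_class[ord]

    half <- function(fams, n) sample(rep(fams, length.out = n))
    rel_fams <- if (rel_dim == "orientation") c("rightward", "leftward") else c("green", "blue")
    irr_fams <- if (is.na(irr_dim)) NA else if (irr_dim == "orientation") c("rightward", "leftward") else c("green", "blue")

    one_dim <- function(class_vec) {
      n <- length(class_vec)
      lower <- sample.int(5L, n, replace = TRUE)
      upper <- lower + 2L
      mean_i <- lower + 1L
      idx <- integer(n)
      is_m <- class_vec == "M"
      is_o <- class_vec == "O"
      is_n <- class_vec == "N"
      idx[is_m] <- mean_i[is_m]
      pick_o <- sample.int(2L, sum(is_o), replace = TRUE)
      idx[is_o] <- ifelse(pick_o == 1L, lower[is_o], upper[is_o])
      if (any(is_n)) {
        idx[is_n] <- vapply(which(is_n), function(i) {
          cand <- setdiff(1:7, c(lower[i], mean_i[i], upper[i]))
          cand[sample.int(4L, 1L)]
        }, integer(1))
      }
      list(lower = lower, upper = upper, idx = idx)
    }

    mk <- function(class_rel, class_irr, n, practice) {
      rel <- one_dim(class_rel)
      rel_ps <- probe_spec(class_rel, rel$idx, rel$lower, rel$upper)
      out <- tibble::tibble(
        participant_id = participant_id,
        experiment = as.integer(experiment),
        practice_flag = practice,
        relevant_dimension = rel_dim,
        family = half(rel_fams, n),
        rel_old_lower = rel$lower,
        rel_old_upper = rel$upper,
        rel_probe_index = rel_ps$series_index,
        relevant_probe_class = rel_ps$probe_class,
        relevant_dist_from_mean = rel_ps$dist_from_mean,
        relevant_dist_from_old = rel_ps$dist_from_old,
        relevant_side = rel_ps$side
      )
      if (!is.na(irr_dim)) {
        irr <- one_dim(class_irr)
        irr_ps <- probe_spec(class_irr, irr$idx, irr$lower, irr$upper)
        out$irrelevant_dimension <- irr_dim
        out$irrelevant_family <- half(irr_fams, n)
        out$irr_old_lower <- irr$lower
        out$irr_old_upper <- irr$upper
        out$irr_probe_index <- irr_ps$series_index
        out$irrelevant_probe_class <- irr_ps$probe_class
        out$irrelevant_dist_from_mean <- irr_ps$dist_from_mean
        out$irrelevant_dist_from_old <- irr_ps$dist_from_old
        out$irrelevant_side <- irr_ps$side
      } else {
        out$irrelevant_dimension <- NA_character_
        out$irrelevant_family <- NA_character_
        out$irr_old_lower <- NA_integer_
        out$irr_old_upper <- NA_integer_
        out$irr_probe_index <- NA_integer_
        out$irrelevant_probe_class <- NA_character_
        out$irrelevant_dist_from_mean <- NA_integer_
        out$irrelevant_dist_from_old <- NA_integer_
        out$irrelevant_side <- NA_character_
      }
      out
    }

    practice <- mk(rel_prac, irr_prac, 20L, TRUE)
    experimental <- mk(rel_class, irr_class, n_exp, FALSE)
    practice$block <- 0L
    practice$trial_index <- 1:20
    experimental$block <- rep(1:5, each = 96L)
    experimental$trial_index <- 1:480
    dplyr::bind_rows(practice, experimental)
  })
  dplyr::relocate(build, "block", "trial_index", .after = "experiment")
}

#' Simulate Yes/No responses for a trial table
#'
#' Draws one binomial response per trial from an observer model (see
#' [observer_averaging()] and [observer_similarity()]). The relevant-rule
#' p(No) is computed from the relevant probe's distances; on factorial
#' designs it is mixed with the irrelevant-dimension p(No) using the
#' observer's `lambda` weight. Responses are drawn on a per-participant
#' seed sub-stream independent of the design stream.
#'
#' @param trials Trial tibble from [generate_session()] (or several bound
#'   together).
#' @param observer An `ec_observer`.
#' @param seed Integer root seed.
#' @return `trials` with columns `p_no_true` (the generating probability)
#'   and `response` (`"Yes"`/`"No"`) appended.
#' @export
simulate_responses <- function(trials, observer, seed = 1) {
  stopifnot(inherits(observer, "ec_observer"))
  p_rel <- prob_for_dimension(observer, trials, prefix = "rel")
  has_irr <- !is.na(trials$irrelevant_probe_class)
  p <- p_rel
  if (any(has_irr) && observer$lambda > 0) {
    irr_obs <- observer$irrelevant %||% observer
    p_irr <- prob_for_dimension(irr_obs, trials[has_irr, ], prefix = "irr")
    p[has_irr] <- (1 - observer$lambda) * p_rel[has_irr] +
      observer$lambda * p_irr
  }
  trials$p_no_true <- p
  trials$response <- NA_character_
  for (pid in unique(trials$participant_id)) {
    rows <- which(trials$participant_id == pid)
    expt <- trials$experiment[rows[1]]
    draw <- with_stream(seed, paste0("response/", expt, "/", pid),
      stats::rbinom(length(rows), 1L, p[rows])
    )
    trials$response[rows] <- ifelse(draw == 1L, "No", "Yes")
  }
  trials
}

# p(No) from one dimension's probe geometry; prefix "rel" or "irr".
prob_for_dimension <- function(observer, trials, prefix) {
  idx <- trials[[paste0(prefix, "_probe_index")]]
  lower <- trials[[paste0(prefix, "_old_lower")]]
  upper <- trials[[paste0(prefix, "_old_upper")]]
  if (observer$rule == "averaging") {
    response_prob(observer, dist_from_mean = abs(idx - (lower + 1L)))
  } else {
    response_prob(observer,
      d_lower = abs(idx - lower), d_upper = abs(idx - upper)
    )
  }
}

#' Simulate a whole experiment
#'
#' Convenience wrapper: generates sessions for `n_participants` and
#' simulates their responses under one observer model.
#'
#' @inheritParams generate_session
#' @inheritParams simulate_responses
#' @param n_participants Number of simulated participants.
#' @return A trial tibble with responses, all participants stacked.
#' @export
#' @examples
#' dat <- simulate_experiment(1, n_participants = 2, seed = 7)
simulate_experiment <- function(experiment, n_participants = 24,
                                observer = observer_averaging(), seed = 1) {
  ids <- sprintf("P%02d", seq_len(n_participants))
  trials <- purrr::map(ids, function(pid) {
    generate_session(experiment, pid, seed = seed)
  })
  simulate_responses(dplyr::bind_rows(trials), observer, seed = seed)
}

#' Generate the spatial layout of a memory display
#'
#' Places the 64 memory bars uniformly at random in the centrally positioned
#' 1000 x 800 unit display region, excluding a central disc whose radius
#' equals one bar length (40 units) so no memory bar can superimpose the
#' subsequent central probe. Exactly half the bars carry each of the two old
#' values on the relevant dimension; on factorial designs the two old values
#' of each dimension are crossed in balance (16 bars per combination). Bars
#' may otherwise overlap.
#'
#' @param trial A one-row trial tibble (from [generate_session()]).
#' @param seed Integer root seed.
#' @return A tibble of 64 rows: `bar`, `x`, `y`, `relevant_level` and
#'   `irrelevant_level` (series indices; irrelevant is `NA` for
#'   single-dimension designs).
#' @export
generate_layout <- function(trial, seed = 1) {
  stopifnot(nrow(trial) == 1)
  width <- 1000; height <- 800; excl <- 40
  stream <- paste0("layout/", trial$experiment, "/", trial$participant_id,
                   "/", trial$block, "/", trial$trial_index)
  with_stream(seed, stream, {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < 64) {
      need <- 64 - length(xs)
      x <- stats::runif(2 * need, 0, width)
      y <- stats::runif(2 * need, 0, height)
      ok <- (x - width / 2)^2 + (y - height / 2)^2 > excl^2
      xs <- c(xs, x[ok])[seq_len(min(64, length(xs) + sum(ok)))]
      ys <- c(ys, y[ok])[seq_len(length(xs))]
    }
    rel_vals <- rep(c(trial$rel_old_lower, trial$rel_old_upper), each = 32)
    irr_vals <- if (!is.na(trial$irrelevant_probe_class)) {
      rep(rep(c(trial$irr_old_lower, trial$irr_old_upper), each = 16), 2)
    } else {
      rep(NA_integer_, 64)
    }
    ord <- sample.int(64)
    tibble::tibble(
      bar = 1:64, x = xs, y = ys,
      relevant_level = rel_vals[ord], irrelevant_level = irr_vals[ord]
    )
  })
}
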