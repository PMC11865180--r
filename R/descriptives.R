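#' Classify a probe relative to its old pair
#'
#' Computes the two ordinal distances the competing hypotheses score trials
#' by: the probe's distance from the (never-shown) mean of the two old
#' items, and its distance from the nearest old item. Vectorised.
#'
#' @param lower_index,upper_index Series indices of the old pair
#'   (`upper = lower + 2`).
#' @param probe_index Series index of the probe.
#' @return A tibble with `dist_from_mean` and `dist_from_old`.
#' @export
#' @examples
#' classify_probe(1, 3, 4) # N probe: 2 steps from the mean, 1 from an old
classify_probe <- function(lower_index, upper_index, probe_index) {
  if (any(upper_index - lower_index != 2)) {
    stop("old pair must be two ordinal steps apart", call. = FALSE)
  }
  tibble::tibble(
    dist_from_mean = abs(probe_index - (lower_index + 1L)),
    dist_from_old = pmin(
      abs(probe_index - lower_index), abs(probe_index - upper_index)
    )
  )
}

# Category label: M, O, or N1..N4 by distance from the nearest old item.
category_label <- function(probe_class, dist_from_old) {
  ifelse(probe_class == "N", paste0("N", dist_from_old), probe_class)
}

#' Per-participant p(No) by probe category
#'
#' Casts trial-level responses as the proportion of "No" responses per probe
#' category under one of the two classificatory schemes. Under `from_mean`
#' (the averaging account) the predictor `x` is the probe's ordinal distance
#' from the mean: M at 0, O at 1, N probes at 2-5. Under `from_old` (the
#' similarity account) `x` is the distance from the nearest old item: O at
#' 0, M and N1 both at 1 (kept as separate rows; psychometric fitting pools
#' them), N2-N4 at 2-4. Practice trials are excluded. Categories with no
#' trials are simply absent from the table — never imputed.
#'
#' @param trials A trial tibble with responses.
#' @param scheme `"from_mean"` or `"from_old"`.
#' @return A tibble: `participant_id`, `experiment`, `scheme`, `category`
#'   (`M`, `O`, `N1`-`N4`), `x`, `n_trials`, `n_no`, `p_no` (an exact
#'   ratio).
#' @export
#' @examples
#' dat <- simulate_experiment(1, n_participants = 1, seed = 3)
#' condition_table(dat, "from_mean")
condition_table <- function(trials, scheme = c("from_mean", "from_old")) {
  scheme <- match.arg(scheme)
  trials |>
    dplyr::filter(!.data$practice_flag) |>
    dplyr::mutate(
      category = category_label(
        .data$relevant_probe_class, .data$relevant_dist_from_old
      ),
      x = if (scheme == "from_mean") {
        .data$relevant_dist_from_mean
      } else {
        .data$relevant_dist_from_old
      }
    ) |>
    dplyr::group_by(
      .data$participant_id, .data$experiment, .data$category, .data$x
    ) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_no = sum(.data$response == "No"),
      .groups = "drop"
    ) |>
    dplyr::mutate(scheme = scheme, p_no = .data$n_no / .data$n_trials) |>
    dplyr::relocate("scheme", .after = "experiment") |>
    dplyr::arrange(.data$participant_id, .data$x, .data$category)
}

#' Apply the chance-performance exclusion rule
#'
#' Participants are excluded when they perform at (or, optionally, strictly
#' worse than) chance on the N probes maximally distant from the mean: with
#' a Yes/No task, chance is p(No) = 0.5, and a competent participant should
#' overwhelmingly reject probes five steps from the mean. The criterion is
#' evaluated on each participant's largest available distance-from-mean N
#' category.
#'
#' @param trials A trial tibble with responses.
#' @param threshold Chance level (default 0.5).
#' @param strict If `FALSE` (default) a participant is excluded when
#'   `p_no <= threshold` ("at chance or worse"); if `TRUE`, only when
#'   `p_no < threshold` ("worse than chance").
#' @return A list: `retained` (trial tibble restricted to retained
#'   participants) and `log` (one row per participant: the category tested,
#'   its `p_no`, and the `excluded` flag).
#' @export
exclude_participants <- function(trials, threshold = 0.5, strict = FALSE) {
  tab <- condition_table(trials, "from_mean")
  log <- tab |>
    dplyr::filter(grepl("^N", .data$category)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::slice_max(.data$x, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      excluded = if (strict) {
        .data$p_no < threshold
      } else {
        .data$p_no <= threshold
      }
    ) |>
    dplyr::select(
      "participant_id", "category", "n_trials", "p_no", "excluded"
    )
  keep <- log$participant_id[!log$excluded]
  list(
    retained = dplyr::filter(trials, .data$participant_id %in% keep),
    log = log
  )
}

#' Similarity-hypothesis point prediction for the mean probe
#'
#' Under the similarity hypothesis the mean probe is confused independently
#' with each old item, and the N1 probes — new probes one step from the
#' nearest old item, hence exactly as far from an old item as the mean probe
#' is — measure those confusabilities. The predicted probability of
#' rejecting the mean probe is therefore the product
#' `p(No|M) = p(No|N1A) * p(No|N1B)` (equivalently, on the Yes scale,
#' `p(Yes|M) = p(Yes|N1A) + p(Yes|N1B) - p(Yes|N1A) * p(Yes|N1B)`).
#'
#' N1A/N1B are the below- and above-range N1 probes. When both sides have at
#' least `n_min` trials (and `n1_policy = "side"`) the two factors are
#' estimated side-specifically; otherwise the pooled N1 proportion stands in
#' for both, giving a squared pooled estimate. Old pairs at the series
#' boundary put all their N probes on one side, so small sessions can starve
#' a side.
#'
#' @param trials A trial tibble with responses (practice excluded
#'   internally).
#' @param n1_policy `"side"` (default) or `"pooled"`.
#' @param n_min Minimum per-side N1 trials for side-specific estimation.
#' @return A tibble, one row per participant: N1 trial counts per side, the
#'   two factor estimates, `p_no_m_pred`, `p_yes_m_pred` (its complement),
#'   the observed `p_no_m_obs`, and the `policy_used`.
#' @export
similarity_prediction <- function(trials, n1_policy = c("side", "pooled"),
                                  n_min = 5) {
  n1_policy <- match.arg(n1_policy)
  dat <- dplyr::filter(trials, !.data$practice_flag)
  dat |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(d, key) {
      n1 <- dplyr::filter(
        d, .data$relevant_probe_class == "N", .data$relevant_dist_from_old == 1
      )
      if (nrow(n1) == 0) {
        stop("no N1 trials for participant ", key$participant_id,
             call. = FALSE)
      }
      m <- dplyr::filter(d, .data$relevant_probe_class == "M")
      p_no <- function(z) mean(z$response == "No")
      a <- dplyr::filter(n1, .data$relevant_side == "below")
      b <- dplyr::filter(n1, .data$relevant_side == "above")
      side_ok <- n1_policy == "side" && nrow(a) >= n_min && nrow(b) >= n_min
      if (side_ok) {
        p_a <- p_no(a); p_b <- p_no(b)
      } else {
        p_a <- p_b <- p_no(n1)
      }
      tibble::tibble(
        n_n1a = nrow(a), n_n1b = nrow(b),
        policy_used = if (side_ok) "side" else "pooled",
        p_no_n1a = p_a, p_no_n1b = p_b,
        p_no_m_pred = predict_similarity_no(p_a, p_b),
        p_yes_m_pred = predict_similarity_yes(1 - p_a, 1 - p_b),
        p_no_m_obs = p_no(m)
      )
    }) |>
    dplyr::ungroup()
}

#' Similarity product prediction (probability forms)
#'
#' The two algebraically equivalent forms of the similarity point
#' prediction: on the No scale, the product of the two N1 rejection
#' probabilities; on the Yes scale, the inclusion-exclusion union of the two
#' N1 acceptance probabilities. They are exact complements:
#' `predict_similarity_yes(1 - p, 1 - q) == 1 - predict_similarity_no(p, q)`.
#'
#' @param p_no_n1a,p_no_n1b Rejection probabilities of the two N1 probes.
#' @param p_yes_n1a,p_yes_n1b Acceptance probabilities of the two N1 probes.
#' @return Predicted p(No|M) or p(Yes|M).
#' @export
#' @examples
#' predict_similarity_no(0.6, 0.5) # 0.30
#' predict_similarity_yes(0.4, 0.4) # 0.64
predict_similarity_no <- function(p_no_n1a, p_no_n1b) {
  stopifnot(all(p_no_n1a >= 0 & p_no_n1a <= 1),
            all(p_no_n1b >= 0 & p_no_n1b <= 1))
  p_no_n1a * p_no_n1b
}

#' @rdname predict_similarity_no
#' @export
predict_similarity_yes <- function(p_yes_n1a, p_yes_n1b) {
  stopifnot(all(p_yes_n1a >= 0 & p_yes_n1a <= 1),
            all(p_yes_n1b >= 0 & p_yes_n1b <= 1))
  p_yes_n1a + p_yes_n1b - p_yes_n1a * p_yes_n1b
}
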