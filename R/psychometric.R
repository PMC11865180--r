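#' Three-parameter log-logistic psychometric function
#'
#' `p(No) = a + (1 - a) / (1 + exp(b - c * x))`, where `x` is the probe's
#' ordinal distance (from the mean under the averaging account, from the
#' nearest old item under the similarity account), `a` is the floor
#' rejection rate, `b` the location and `c >= 0` the slope. As `x` grows the
#' function rises from `a` towards 1. The complementary acceptance
#' probability is defined as `p(Yes) = 1 - p(No)`.
#'
#' @param x Ordinal distance (numeric vector).
#' @param a,b,c Parameters (`0 <= a <= 1`, `c >= 0`).
#' @return p(No) values.
#' @export
#' @examples
#' loglogistic(0:5, a = 0.2, b = 0, c = 1)
loglogistic <- function(x, a, b, c) {
  stopifnot(a >= 0, a <= 1, c >= 0)
  a + (1 - a) / (1 + exp(b - c * x))
}

# Fixed multi-start grid (coarse 4 x 4 x 4 over plausible ranges).
fit_start_grid <- function() {
  as.matrix(tidyr::expand_grid(
    a = seq(0, 0.6, length.out = 4),
    b = seq(-2, 6, length.out = 4),
    c = seq(0.1, 4, length.out = 4)
  ))
}

# Weighted-least-squares fit of the log-logistic to (x, p, w) points.
# Deterministic: full grid is screened, then bounded optimisation is run
# from the best `n_starts` grid points and the best optimum kept.
fit_loglogistic_points <- function(x, p, w, n_starts = 3) {
  w <- w / mean(w)
  rss_fun <- function(par) {
    pred <- par[1] + (1 - par[1]) / (1 + exp(par[2] - par[3] * x))
    sum(w * (p - pred)^2)
  }
  grid <- fit_start_grid()
  grid_rss <- apply(grid, 1, rss_fun)
  starts <- grid[order(grid_rss)[seq_len(n_starts)], , drop = FALSE]
  best <- NULL
  converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    opt <- try(stats::optim(
      starts[i, ], rss_fun, method = "L-BFGS-B",
      lower = c(0, -20, 0), upper = c(1, 20, 20),
      control = list(factr = 1e5)
    ), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) {
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                rss = NA_real_, converged = FALSE, degenerate = TRUE))
  }
  tss <- sum(w * (p - stats::weighted.mean(p, w))^2)
  list(
    a = unname(best$par[1]), b = unname(best$par[2]),
    c = unname(best$par[3]),
    rss = best$value,
    r_squared = if (tss > 0) 1 - best$value / tss else NA_real_,
    converged = converged,
    degenerate = tss == 0 || best$par[3] < 1e-6
  )
}

#' Fit the log-logistic under a classificatory scheme
#'
#' Fits each participant's per-category p(No) proportions with the
#' log-logistic of ordinal distance, by weighted least squares with the
#' category trial counts as weights (normalised to mean 1, so RSS is on the
#' same scale as unweighted). Under `from_mean` the fitted categories are
#' `x = 0` (M), 1 (O) and 2-5 (N by distance from the mean); under
#' `from_old` they are `x = 0` (O), 1 (M and N1, pooled into a single
#' count-weighted point by default) and 2-4 (N2-N4). Optimisation is a
#' bounded local search started from a fixed coarse grid, so repeated fits
#' are identical. Gaussian least-squares BIC and r-squared are attached.
#'
#' @param cond_tab Output of [condition_table()] (one or both schemes, any
#'   number of participants).
#' @param pool_m_n1 Pool M with N1 at `x = 1` in the `from_old` scheme
#'   (default `TRUE`; `FALSE` keeps them as two points for sensitivity
#'   analysis).
#' @param min_points Minimum categories with data required to fit.
#' @return An `ec_fits` tibble, one row per participant x scheme:
#'   parameters, `rss`, `r_squared`, `bic`, `n_points`, `converged`,
#'   `degenerate`.
#' @export
#' @examples
#' dat <- simulate_experiment(1, n_participants = 2, seed = 5)
#' fits <- fit_psychometric(condition_table(dat, "from_mean"))
fit_psychometric <- function(cond_tab, pool_m_n1 = TRUE, min_points = 4) {
  out <- cond_tab |>
    dplyr::group_by(.data$participant_id, .data$scheme) |>
    dplyr::group_modify(function(d, key) {
      if (key$scheme == "from_old" && pool_m_n1) {
        d <- d |>
          dplyr::group_by(.data$x) |>
          dplyr::summarise(
            n_trials = sum(.data$n_trials),
            n_no = sum(.data$n_no), .groups = "drop"
          ) |>
          dplyr::mutate(p_no = .data$n_no / .data$n_trials)
      }
      if (nrow(d) < min_points) {
        stop("fewer than ", min_points, " categories with data for ",
             key$participant_id, " (", key$scheme, ")", call. = FALSE)
      }
      f <- fit_loglogistic_points(d$x, d$p_no, d$n_trials)
      tibble::tibble(
        a = f$a, b = f$b, c = f$c, rss = f$rss,
        r_squared = f$r_squared,
        bic = bic_gaussian(f$rss, nrow(d)),
        n_points = nrow(d),
        converged = f$converged, degenerate = f$degenerate
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("ec_fits", class(out))
  out
}

#' Gaussian least-squares BIC
#'
#' `BIC = n * ln(RSS / n) + k * ln(n)` with `k = 3` free parameters and `n`
#' the number of fitted points. A perfect fit (`RSS = 0`) returns `-Inf`
#' with a message, since the criterion is undefined there.
#'
#' @param rss Residual sum of squares.
#' @param n Number of fitted points.
#' @param k Number of free parameters.
#' @return The BIC value.
#' @export
#' @examples
#' bic_gaussian(0.005, 5) # 5 * log(0.001) + 3 * log(5)
bic_gaussian <- function(rss, n, k = 3) {
  stopifnot(rss >= 0, n > 0)
  if (rss == 0) {
    message("RSS = 0: BIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + k * log(n)
}

#' Binomial-likelihood BIC for a fitted participant
#'
#' Alternative BIC formulation using the exact binomial log-likelihood of
#' the per-category No counts under the fitted curve:
#' `BIC = -2 * logLik + k * ln(N)` with `N` the total trial count. Selectable
#' in place of the Gaussian RSS form when comparing schemes on trial-level
#' evidence.
#'
#' @param x,n_no,n_trials Per-category distances, No counts and trial
#'   counts.
#' @param a,b,c Fitted parameters.
#' @param k Number of free parameters.
#' @return The BIC value.
#' @export
bic_binomial <- function(x, n_no, n_trials, a, b, c, k = 3) {
  p <- pmin(pmax(loglogistic(x, a, b, c), 1e-12), 1 - 1e-12)
  ll <- sum(stats::dbinom(n_no, n_trials, p, log = TRUE))
  -2 * ll + k * log(sum(n_trials))
}

#' Compare the two classificatory schemes by BIC
#'
#' Pairs each participant's BIC under the averaging (`from_mean`) and
#' similarity (`from_old`) classifications and tests the difference with a
#' paired t-test (positive t means the `from_old` fit is better, i.e. has
#' the lower BIC). Mean r-squared and mean BIC per scheme are attached as
#' columns.
#'
#' @param fits An `ec_fits` tibble containing both schemes for every
#'   participant.
#' @inheritParams paired_t
#' @return A one-row tibble: the paired test on `bic_from_mean -
#'   bic_from_old` plus per-scheme summary columns.
#' @export
compare_schemes <- function(fits, r_scale = sqrt(2) / 2, bf = TRUE) {
  wide <- fits |>
    dplyr::select("participant_id", "scheme", "bic", "r_squared") |>
    tidyr::pivot_wider(
      names_from = "scheme", values_from = c("bic", "r_squared")
    )
  if (!all(c("bic_from_mean", "bic_from_old") %in% names(wide)) ||
      anyNA(wide$bic_from_mean) || anyNA(wide$bic_from_old)) {
    stop("both schemes must be fitted for every participant", call. = FALSE)
  }
  test <- paired_t(
    wide$bic_from_mean, wide$bic_from_old,
    r_scale = r_scale, bf = bf,
    comparison = "BIC(from_mean) - BIC(from_old)"
  )
  dplyr::mutate(
    test,
    mean_bic_from_mean = mean(wide$bic_from_mean),
    mean_bic_from_old = mean(wide$bic_from_old),
    mean_r2_from_mean = mean(wide$r_squared_from_mean),
    mean_r2_from_old = mean(wide$r_squared_from_old)
  )
}
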