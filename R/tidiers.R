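#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `ec_anova` object.
#' @param ... Unused.
#' @return `tidy()`: one row per effect (`effect`, `df1`, `df2`,
#'   `statistic`, `p_value`). `glance()`: a one-row design summary with the
#'   Tukey chain(s).
#' @export
tidy.ec_anova <- function(x, ...) x$effects

#' @rdname tidy.ec_anova
#' @export
glance.ec_anova <- function(x, ...) {
  tibble::tibble(
    design = x$design, n = x$n,
    n_effects = nrow(x$effects),
    chain = paste(x$chain, collapse = "; ")
  )
}

#' Tidy psychometric fits
#'
#' @param x An `ec_fits` tibble from [fit_psychometric()].
#' @param ... Unused.
#' @return `tidy()`: one row per participant, scheme and parameter.
#'   `glance()`: per-scheme means of BIC and r-squared.
#' @export
tidy.ec_fits <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      c("a", "b", "c"), names_to = "parameter", values_to = "estimate"
    ) |>
    dplyr::select(
      "participant_id", "scheme", "parameter", "estimate", "rss", "bic"
    )
}

#' @rdname tidy.ec_fits
#' @export
glance.ec_fits <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$scheme) |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      mean_bic = mean(.data$bic),
      mean_r_squared = mean(.data$r_squared),
      n_degenerate = sum(.data$degenerate),
      .groups = "drop"
    )
}

#' Tidy a power-simulation result
#'
#' @param x An `ec_power` object from [run_power()].
#' @param ... Unused.
#' @return `tidy()`: the power-by-group-size table. `glance()`: a one-row
#'   configuration summary.
#' @export
tidy.ec_power <- function(x, ...) x$table

#' @rdname tidy.ec_power
#' @export
glance.ec_power <- function(x, ...) {
  tibble::tibble(
    preset = x$config$preset,
    generating_rule = x$config$generating_rule,
    trials_per_condition = x$config$trials_per_condition,
    n_bootstrap = x$config$n_bootstrap,
    min_power = min(x$table$power),
    max_power = max(x$table$power)
  )
}
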