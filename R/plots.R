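#' Plot fitted psychometric functions
#'
#' Draws each participant's fitted log-logistic p(No) curve against ordinal
#' distance, faceted by classificatory scheme; when the condition table the
#' fits came from is supplied, the per-category proportions are overlaid as
#' points sized by trial count.
#'
#' @param object An `ec_fits` tibble.
#' @param cond_tab Optional [condition_table()] output to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ec_fits <- function(object, cond_tab = NULL, ...) {
  grid <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$a)) |>
    dplyr::mutate(curve = purrr::pmap(
      list(.data$a, .data$b, .data$c),
      function(a, b, c) {
        tibble::tibble(x = seq(0, 5, by = 0.1), p_no = loglogistic(seq(0, 5, by = 0.1), a, b, c))
      }
    )) |>
    dplyr::select("participant_id", "scheme", "curve") |>
    tidyr::unnest("curve")
  p <- ggplot2::ggplot(grid, ggplot2::aes(
    x = .data$x, y = .data$p_no, group = .data$participant_id
  )) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "ordinal distance (steps)", y = "p(No)",
      title = "Log-logistic fits by classificatory scheme"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(cond_tab)) {
    p <- p + ggplot2::geom_point(
      data = cond_tab,
      ggplot2::aes(size = .data$n_trials, group = .data$participant_id),
      alpha = 0.4
    ) +
      ggplot2::scale_size_area(max_size = 3)
  }
  p
}

#' Plot a power curve
#'
#' Power of BIC scheme recovery against group size, with the Monte-Carlo
#' confidence ribbon and a reference line at 0.95.
#'
#' @param object An `ec_power` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ec_power <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(
    x = .data$group_size, y = .data$power
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi), alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$table$group_size) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "group size (participants)",
      y = "power (generating scheme recovered by BIC)",
      title = sprintf("Model-selection power (%s preset)",
                      object$config$preset)
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean p(No) by probe category
#'
#' Group mean (and standard error) of the per-participant proportion of No
#' responses against ordinal distance, one panel per classificatory scheme.
#'
#' @param cond_tab Output of [condition_table()] (either or both schemes).
#' @return A ggplot object.
#' @export
plot_condition_means <- function(cond_tab) {
  summ <- cond_tab |>
    dplyr::group_by(.data$scheme, .data$x, .data$category) |>
    dplyr::summarise(
      mean_p_no = mean(.data$p_no),
      se = stats::sd(.data$p_no) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$x, y = .data$mean_p_no, label = .data$category
  )) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_p_no - .data$se, ymax = .data$mean_p_no + .data$se
    )) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "ordinal distance (steps)", y = "mean p(No)") +
    ggplot2::theme_minimal()
}
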