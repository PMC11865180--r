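#' Canonical 7-level feature series
#'
#' Each experiment samples its memory items from an ordered series of seven
#' feature values: orientations from 0 to 90 degrees in 15-degree steps
#' (tilted rightward or leftward), or seven luminance levels of one hue
#' family (green or blue) with chromaticity held fixed. The colour levels are
#' read from the packaged colorimetry table (see [color_series_table()]).
#'
#' @param dimension `"orientation"` or `"color"`.
#' @param family `"rightward"`/`"leftward"` for orientation,
#'   `"green"`/`"blue"` for colour.
#' @return A tibble with one row per series level: `dimension`, `family`,
#'   `level` (1-7, the ordinal position) and `value` (degrees, or luminance Y
#'   for colour; colour rows also carry the sRGB `hex` code).
#' @export
#' @examples
#' make_series("orientation", "rightward")
#' make_series("color", "green")
make_series <- function(dimension = c("orientation", "color"),
                        family = NULL) {
  dimension <- match.arg(dimension)
  if (dimension == "orientation") {
    family <- family %||% "rightward"
    if (!family %in% c("rightward", "leftward")) {
      stop("unknown orientation family: ", family, call. = FALSE)
    }
    tibble::tibble(
      dimension = dimension, family = family,
      level = 1:7, value = seq(0, 90, by = 15)
    )
  } else {
    family <- family %||% "green"
    if (!family %in% c("green", "blue")) {
      stop("unknown color family: ", family, call. = FALSE)
    }
    tab <- color_series_table()
    tab <- tab[tab$family == family, ]
    tibble::tibble(
      dimension = dimension, family = family,
      level = tab$level, value = tab$Y, hex = tab$hex
    )
  }
}

#' Packaged colour-series colorimetry table
#'
#' The two 7-level colour series (green and blue). Within a series the
#' chromaticity coordinates (x, y) are approximately constant while luminance
#' Y increases strictly, so the ordinal series structure lives on luminance.
#' Columns: CIE xyY, CIE L*a*b*, sRGB 0-255 triples and hex codes.
#'
#' @return A tibble with 14 rows (two families x seven levels).
#' @export
color_series_table <- function() {
  path <- system.file("extdata", "color_series.csv", package = "ensembleYN")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Sample an old pair from a series
#'
#' The two "old" feature values shown in the memory display are two series
#' levels two ordinal steps apart (30 degrees for orientation, two luminance
#' steps for colour), leaving exactly one intervening level that defines the
#' mean. The lower index is uniform over positions 1-5.
#'
#' @param seed Integer seed (optional). When `NULL` the current RNG state is
#'   used.
#' @return A one-row tibble: `lower_index`, `mean_index`, `upper_index`.
#' @export
sample_old_pair <- function(seed = NULL) {
  draw <- function() sample.int(5L, 1L)
  lower <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::tibble(
    lower_index = lower, mean_index = lower + 1L, upper_index = lower + 2L
  )
}

#' Assign a probe of a given class to an old pair
#'
#' The probe carries the never-shown mean value (class `"M"`), one of the two
#' shown old values (`"O"`, chosen uniformly), or a new value outside the old
#' range (`"N"`, uniform over the four series levels that are neither old nor
#' the mean). Ordinal distances are computed from the series indices:
#' `dist_from_mean` is the distance to the mean level, `dist_from_old` the
#' distance to the nearest old level. `side` locates N probes below or above
#' the old range.
#'
#' @param probe_class `"M"`, `"O"` or `"N"`.
#' @param old_pair One-row tibble from [sample_old_pair()].
#' @param seed Optional integer seed.
#' @return A one-row tibble: `probe_class`, `series_index`, `dist_from_mean`,
#'   `dist_from_old`, `side`.
#' @export
#' @examples
#' assign_probe("M", sample_old_pair(seed = 1))
assign_probe <- function(probe_class = c("M", "O", "N"), old_pair,
                         seed = NULL) {
  probe_class <- match.arg(probe_class)
  lower <- old_pair$lower_index[1]
  upper <- old_pair$upper_index[1]
  mean_i <- old_pair$mean_index[1]
  draw <- function() {
    switch(probe_class,
      M = mean_i,
      O = c(lower, upper)[sample.int(2L, 1L)],
      N = {
        cand <- setdiff(1:7, c(lower, mean_i, upper))
        cand[sample.int(length(cand), 1L)]
      }
    )
  }
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  probe_spec(probe_class, idx, lower, upper)
}

# Build a ProbeSpec row from indices (vectorised).
probe_spec <- function(probe_class, series_index, lower, upper) {
  mean_i <- lower + 1L
  tibble::tibble(
    probe_class = probe_class,
    series_index = as.integer(series_index),
    dist_from_mean = abs(series_index - mean_i),
    dist_from_old = pmin(abs(series_index - lower), abs(series_index - upper)),
    side = dplyr::case_when(
      probe_class != "N" ~ "n/a",
      series_index < lower ~ "below",
      TRUE ~ "above"
    )
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
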