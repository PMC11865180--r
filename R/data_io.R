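canonical_cols <- c(
  "participant_id", "experiment", "block", "trial_index", "practice_flag",
  "relevant_dimension", "relevant_probe_class", "relevant_dist_from_mean",
  "relevant_dist_from_old", "relevant_side", "irrelevant_probe_class",
  "irrelevant_dist_from_mean", "irrelevant_dist_from_old", "family",
  "response"
)

#' Validate a trial table
#'
#' Checks the canonical trial-table invariants: responses are `"Yes"` or
#' `"No"`; probe classes and ordinal distances are mutually consistent
#' (M probes sit on the mean, one step from the nearest old item; O probes
#' on an old item, one step from the mean; N probes one to four steps
#' outside the old range, with distance-from-mean one greater than
#' distance-from-old); and no participant has more than 480 non-practice
#' trials per experiment. Violating rows are reported by row number.
#'
#' @param trials A trial tibble.
#' @return `trials`, invisibly, if valid; otherwise an error listing the
#'   offending rows.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(canonical_cols, names(trials))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- character(0)
  note <- function(rows, why) {
    if (length(rows) > 0) {
      bad <<- c(bad, sprintf(
        "%s (rows %s)", why,
        paste(utils::head(rows, 5), collapse = ", ")
      ))
    }
  }
  note(which(!trials$response %in% c("Yes", "No")), "response not Yes/No")
  cls <- trials$relevant_probe_class
  dm <- trials$relevant_dist_from_mean
  do <- trials$relevant_dist_from_old
  note(which(cls == "M" & !(dm == 0 & do == 1)), "M probe distances not (0, 1)")
  note(which(cls == "O" & !(dm == 1 & do == 0)), "O probe distances not (1, 0)")
  note(
    which(cls == "N" & !(do %in% 1:4 & dm == do + 1)),
    "N probe distances inconsistent"
  )
  counts <- dplyr::count(
    dplyr::filter(trials, !.data$practice_flag),
    .data$participant_id, .data$experiment
  )
  if (any(counts$n > 480)) {
    bad <- c(bad, "a participant has more than 480 non-practice trials")
  }
  if (length(bad) > 0) {
    stop("invalid trial table: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  invisible(trials)
}

#' Write a trial table to CSV
#'
#' Writes the canonical comma-separated serialisation (UTF-8, RFC 4180,
#' fixed header), validating first. Optional series-index columns
#' (`rel_old_lower`, ...) are preserved when present, so a written file
#' round-trips losslessly through [read_trials()].
#'
#' @param trials A valid trial tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (nrow(trials) > 0) validate_trials(trials)
  keep <- c(
    canonical_cols,
    intersect(
      c("rel_old_lower", "rel_old_upper", "rel_probe_index",
        "irr_old_lower", "irr_old_upper", "irr_probe_index",
        "irrelevant_dimension", "irrelevant_family", "irrelevant_side",
        "p_no_true"),
      names(trials)
    )
  )
  keep <- intersect(keep, names(trials))
  readr::write_csv(trials[, keep, drop = FALSE], path, progress = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads a canonical file from [write_trials()], or any trial-level CSV via
#' a column mapping that renames source columns and recodes response values
#' (see [read_mapping()]). When the file carries raw series indices
#' (`rel_old_lower`, `rel_old_upper`, `rel_probe_index`, and the `irr_`
#' counterparts) the ordinal distances and probe sides are recomputed from
#' them, which both fills schema gaps in the source and guards against
#' inconsistent distance columns. The result is validated before return;
#' rows with a missing response are dropped with a message.
#'
#' @param path CSV file path.
#' @param mapping Optional mapping, as returned by [read_mapping()]: a list
#'   with `columns` (named character vector, canonical = source) and
#'   optionally `values$response` (named vector recoding source response
#'   codes to `"Yes"`/`"No"`).
#' @return A validated trial tibble.
#' @export
read_trials <- function(path, mapping = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(mapping)) {
    cols <- mapping$columns
    for (canonical in names(cols)) {
      src <- cols[[canonical]]
      if (!src %in% names(raw)) {
        stop("mapped source column not found: ", src, call. = FALSE)
      }
      raw[[canonical]] <- raw[[src]]
    }
    rec <- mapping$values$response
    if (!is.null(rec)) {
      codes <- as.character(raw$response)
      unknown <- setdiff(unique(codes), names(rec))
      if (length(unknown) > 0) {
        stop("unmappable response code(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      raw$response <- unname(unlist(rec)[codes])
    }
  }
  essential <- c("participant_id", "response")
  absent <- setdiff(essential, names(raw))
  if (length(absent) > 0) {
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (!"practice_flag" %in% names(raw)) raw$practice_flag <- FALSE
  if (!"block" %in% names(raw)) raw$block <- NA_integer_
  if (!"trial_index" %in% names(raw)) raw$trial_index <- seq_len(nrow(raw))

  has_idx <- all(c("rel_old_lower", "rel_old_upper", "rel_probe_index") %in%
                   names(raw))
  if (has_idx) {
    ps <- probe_spec(
      raw$relevant_probe_class %||% NA_character_,
      raw$rel_probe_index, raw$rel_old_lower, raw$rel_old_upper
    )
    if (!"relevant_probe_class" %in% names(raw)) {
      raw$relevant_probe_class <- dplyr::case_when(
        ps$dist_from_mean == 0 ~ "M", ps$dist_from_old == 0 ~ "O", TRUE ~ "N"
      )
      ps$side <- ifelse(raw$relevant_probe_class == "N", ps$side, "n/a")
    }
    raw$relevant_dist_from_mean <- ps$dist_from_mean
    raw$relevant_dist_from_old <- ps$dist_from_old
    raw$relevant_side <- ps$side
  }
  has_irr_idx <- all(c("irr_old_lower", "irr_old_upper", "irr_probe_index") %in%
                       names(raw)) && !all(is.na(raw$irr_probe_index))
  if (has_irr_idx) {
    ok <- !is.na(raw$irr_probe_index)
    ps <- probe_spec(
      raw$irrelevant_probe_class[ok],
      raw$irr_probe_index[ok], raw$irr_old_lower[ok], raw$irr_old_upper[ok]
    )
    raw$irrelevant_dist_from_mean[ok] <- ps$dist_from_mean
    raw$irrelevant_dist_from_old[ok] <- ps$dist_from_old
  }
  for (col in setdiff(canonical_cols, names(raw))) {
    raw[[col]] <- if (col %in% c("practice_flag")) FALSE else NA
  }
  # all-NA columns come back untyped from CSV; pin the canonical types
  chr_cols <- c(
    "participant_id", "relevant_dimension", "relevant_probe_class",
    "relevant_side", "irrelevant_probe_class", "family", "response",
    "irrelevant_dimension", "irrelevant_family", "irrelevant_side"
  )
  int_cols <- c(
    "experiment", "block", "trial_index", "relevant_dist_from_mean",
    "relevant_dist_from_old", "irrelevant_dist_from_mean",
    "irrelevant_dist_from_old", "rel_old_lower", "rel_old_upper",
    "rel_probe_index", "irr_old_lower", "irr_old_upper", "irr_probe_index"
  )
  for (col in intersect(chr_cols, names(raw))) {
    raw[[col]] <- as.character(raw[[col]])
  }
  for (col in intersect(int_cols, names(raw))) {
    raw[[col]] <- as.integer(raw[[col]])
  }
  raw$practice_flag <- as.logical(raw$practice_flag)
  n_missing <- sum(is.na(raw$response))
  if (n_missing > 0) {
    message("dropping ", n_missing, " trial(s) with no response")
    raw <- raw[!is.na(raw$response), ]
  }
  validate_trials(raw)
  tibble::as_tibble(raw)
}

#' Read a column-mapping configuration
#'
#' Mapping files adapt externally deposited trial-level data to the
#' canonical schema without editing the data themselves. YAML or JSON, with
#' a `columns` block (canonical name = source name) and an optional
#' `values: response:` block recoding response codes (e.g. `"1": Yes`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A mapping list for [read_trials()].
#' @export
read_mapping <- function(path) {
  mapping <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 reads bare Yes/No as booleans; undo that for response recodes
  rec <- mapping$values$response
  if (!is.null(rec)) {
    mapping$values$response <- lapply(rec, function(v) {
      if (is.logical(v)) ifelse(v, "Yes", "No") else as.character(v)
    })
  }
  mapping
}
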