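# Plain-text readers/writers for every on-disk format: choice data and
# event tables as TSV ("." for missing), motion parameters as 6-column
# whitespace text, clinical tables as CSV with an advisory range check.

choice_cols <- c("subject_id", "run", "trial", "stim_left", "stim_mid",
                 "stim_right", "chosen", "feedback", "responded",
                 "lag_chosen")

#' Write / read choice data as TSV
#'
#' Tab-separated, one header row, UTF-8, `.` for missing values. Reading
#' validates the schema strictly: required columns, trial ordering, and
#' that every responded trial's choice is among the offered stimuli
#' (violations are reported with their row numbers).
#'
#' @param choices A choice dataset tibble.
#' @param path File path.
#' @return `write_choices()` returns `path` invisibly; `read_choices()`
#'   returns an `nb_choices` tibble.
#' @export
write_choices <- function(choices, path) {
  cols <- intersect(c(choice_cols, "prob_chosen"), names(choices))
  out <- as.data.frame(choices[, cols])
  out$responded <- as.integer(out$responded)
  # 9 decimals survive a write/read/write cycle byte-identically
  if ("prob_chosen" %in% names(out)) {
    out$prob_chosen <- round(out$prob_chosen, 9)
  }
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  d <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                       progress = FALSE)
  missing_cols <- setdiff(choice_cols, names(d))
  if (length(missing_cols)) {
    abort(sprintf("schema error: missing column(s) %s",
                  paste(missing_cols, collapse = ", ")))
  }
  d$responded <- as.logical(d$responded)
  for (id in unique(d$subject_id)) {
    tr <- d$trial[d$subject_id == id]
    if (is.unsorted(tr, strictly = TRUE)) {
      abort(sprintf("schema error: trials of subject %s not strictly increasing.", id))
    }
  }
  offered <- as.matrix(d[, c("stim_left", "stim_mid", "stim_right")])
  bad <- which(d$responded & !is.na(d$chosen) &
                 d$chosen != offered[, 1L] & d$chosen != offered[, 2L] &
                 d$chosen != offered[, 3L])
  if (length(bad)) {
    abort(sprintf("schema error: chosen stimulus not among offered at row(s) %s",
                  paste(head(bad + 1L, 5L), collapse = ", ")))
  }
  if (any(d$responded & is.na(d$feedback))) {
    abort("schema error: responded trials must have feedback.")
  }
  class(d) <- c("nb_choices", class(d))
  d
}

#' Write / read BIDS-style event tables
#'
#' Columns `onset`, `duration`, `trial_type`, plus `run` and `modulator`;
#' TSV with `n/a` for missing, per the BIDS events dialect.
#'
#' @param events An `nb_events` tibble.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  readr::write_tsv(as.data.frame(events), path, na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  d <- readr::read_tsv(path, na = c("n/a", "NA"), show_col_types = FALSE,
                       progress = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(d))) {
    abort(sprintf("schema error: events need columns %s",
                  paste(need, collapse = ", ")))
  }
  if (!"run" %in% names(d)) d$run <- 1L
  if (is.unsorted(d$onset[d$run == d$run[1L]])) {
    abort("schema error: onsets must be non-decreasing within run.")
  }
  class(d) <- c("nb_events", class(d))
  d
}

#' Read a 6-column motion-parameter file
#'
#' Whitespace-separated text, one row per volume, six columns (three
#' translations and three rotations in mm-equivalent units).
#'
#' @param path File path.
#' @return (volumes x 6) numeric matrix.
#' @export
read_motion <- function(path) {
  d <- utils::read.table(path, header = FALSE)
  if (ncol(d) != 6L) {
    abort(sprintf("format error: motion file must have 6 columns, found %d.",
                  ncol(d)))
  }
  as.matrix(d)
}

#' Write a motion-parameter matrix
#'
#' @param motion (volumes x 6) matrix.
#' @param path File path.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(motion, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a clinical table (CSV)
#'
#' Requires `subject_id`, `audit_raw`, `cudit_raw`, `sex`; extra columns
#' pass through. Values outside the instruments' ranges (AUDIT 0-34,
#' CUDIT 0-32) raise an advisory warning but are retained.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_clinical <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "audit_raw", "cudit_raw", "sex")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    abort(sprintf("schema error: missing column(s) %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(d$audit_raw < 0 | d$audit_raw > 34, na.rm = TRUE)) {
    warn("AUDIT values outside the instrument range 0-34 (retained).")
  }
  if (any(d$cudit_raw < 0 | d$cudit_raw > 32, na.rm = TRUE)) {
    warn("CUDIT values outside the instrument range 0-32 (retained).")
  }
  if (!all(d$sex %in% c(0L, 1L, NA))) {
    abort("schema error: sex must be coded 1 = male, 0 = female.")
  }
  d
}
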