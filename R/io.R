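#' Read and write the person and event tables
#'
#' The on-disk interchange format is plain CSV with fixed headers:
#' persons carry `person_id, practice_id, sex, entry_age, end_age`, events
#' carry `person_id, chapter, event_class, event_age`. Generator truth
#' columns, if present, are dropped on write; exposure status is always
#' re-derived from the event records by the case algorithms.
#'
#' @param persons,events Data frames as produced by [generate_population()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a data frame.
#' @name ehr_io
NULL

#' @rdname ehr_io
#' @export
write_persons <- function(persons, path) {
  cols <- c("person_id", "practice_id", "sex", "entry_age", "end_age")
  check_columns(persons, cols, "persons")
  utils::write.csv(persons[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ehr_io
#' @export
write_events <- function(events, path) {
  cols <- c("person_id", "chapter", "event_class", "event_age")
  check_columns(events, cols, "events")
  utils::write.csv(events[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ehr_io
#' @export
read_persons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("person_id", "practice_id", "sex", "entry_age", "end_age"),
                "persons")
  df
}

#' @rdname ehr_io
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("person_id", "chapter", "event_class", "event_age"),
                "events")
  df
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
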