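# CSV surfaces. Observations travel in long format (patient_id, timestamp,
# variable, value): irregular reading times and partial panels fit naturally,
# and only offsets from each patient's first record (the admission panel)
# matter for windowing. Timestamps are handled timezone-naive.

obs_epoch <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")

#' Write / read a long-format observation CSV
#'
#' Columns: `patient_id`, `timestamp` (ISO-8601), `variable`, `value`.
#' Admission is each patient's earliest timestamp; `read_observations()`
#' converts timestamps to fractional hours from admission (`time_h`).
#' Unknown variables, enum tokens outside the scoresheet vocabulary and
#' duplicate (patient, time, variable) rows are rejected with row numbers.
#'
#' @param obs long observations with `patient_id`, `time_h`, `variable`,
#'   `value`.
#' @param path CSV path.
#' @return `write_observations()` the path, invisibly; `read_observations()`
#'   a data.frame with `patient_id`, `time_h`, `variable`, `value`.
#' @export
write_observations <- function(obs, path) {
  obs <- as.data.frame(obs)
  stopifnot(all(c("patient_id", "time_h", "variable", "value") %in% names(obs)))
  out <- data.frame(
    patient_id = obs$patient_id,
    timestamp = format(obs_epoch + round(obs$time_h * 3600),
                       "%Y-%m-%dT%H:%M:%S"),
    variable = obs$variable, value = as.character(obs$value),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("patient_id", "timestamp", "variable", "value")
  if (!all(req %in% names(df)))
    stop("observation CSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- which(is.na(ts))
  if (length(bad) > 0L)
    stop("unparseable timestamp(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  known <- c(incns_snapshot_fields, comparator_extra_fields)
  bad <- which(!df$variable %in% known)
  if (length(bad) > 0L)
    stop("unknown variable(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(unique(df$variable[utils::head(bad, 5)]), collapse = ", "),
         call. = FALSE)
  for (nm in intersect(unique(df$variable), names(snapshot_enum_values))) {
    rows <- which(df$variable == nm &
                    !df$value %in% snapshot_enum_values[[nm]])
    if (length(rows) > 0L)
      stop(sprintf("invalid token for '%s' at row(s) %s: %s", nm,
                   paste(utils::head(rows, 5), collapse = ", "),
                   paste(unique(df$value[utils::head(rows, 5)]),
                         collapse = ", ")), call. = FALSE)
  }
  num_since <- as.numeric(ts)
  adm <- tapply(num_since, df$patient_id, min)
  time_h <- (num_since - adm[df$patient_id]) / 3600
  out <- data.frame(patient_id = df$patient_id,
                    time_h = round(as.numeric(time_h), 6),
                    variable = df$variable, value = df$value,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("patient_id", "time_h", "variable")])) {
    dup <- which(duplicated(out[, c("patient_id", "time_h", "variable")]))
    stop("duplicate (patient, time, variable) row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write / read an outcome CSV (`patient_id`, `mrs_3month`)
#'
#' @param outcomes data.frame with `patient_id` and `mrs_3month`.
#' @param path CSV path.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes[, c("patient_id", "mrs_3month")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "mrs_3month") %in% names(df)))
    stop("outcome CSV needs columns patient_id, mrs_3month", call. = FALSE)
  outcome_records(df$patient_id, df$mrs_3month)
}
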