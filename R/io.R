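#' Write / read the raw-walk CSV dialect
#'
#' Columns `timestamp_s, accel_x_g, accel_y_g, accel_z_g`, one row per
#' 80-Hz sample. Subject metadata travels outside the CSV and is supplied
#' on read.
#'
#' @param recording A `walk_recording`.
#' @param path Output file.
#' @export
write_walk_csv <- function(recording, path) {
  stopifnot(inherits(recording, "walk_recording"))
  utils::write.csv(
    data.frame(timestamp_s = recording$timestamp_s,
               accel_x_g = recording$accel_x_g,
               accel_y_g = recording$accel_y_g,
               accel_z_g = recording$accel_z_g),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_walk_csv
#' @param path Input file.
#' @param subject_id,sex,completion_time_s Subject metadata to attach.
#' @export
read_walk_csv <- function(path, subject_id = "unknown",
                          sex = c("female", "male"),
                          completion_time_s = NA_real_) {
  sex <- match.arg(sex)
  d <- utils::read.csv(path)
  need <- c("timestamp_s", "accel_x_g", "accel_y_g", "accel_z_g")
  if (!all(need %in% names(d))) {
    stop("walk CSV must have columns: ", paste(need, collapse = ", "))
  }
  structure(
    list(timestamp_s = d$timestamp_s, accel_x_g = d$accel_x_g,
         accel_y_g = d$accel_y_g, accel_z_g = d$accel_z_g,
         fs = 1 / stats::median(diff(d$timestamp_s)),
         subject_id = subject_id, sex = sex,
         completion_time_s = completion_time_s),
    class = "walk_recording"
  )
}

#' Write / read a cadence-series CSV (`time_s, cadence_spm, flag`)
#'
#' @param cadence A `cadence_series`.
#' @param path File path.
#' @export
write_cadence_csv <- function(cadence, path) {
  utils::write.csv(as.data.frame(cadence)[, c("time_s", "cadence_spm", "flag")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cadence_csv
#' @export
read_cadence_csv <- function(path) {
  d <- utils::read.csv(path)
  d$flag <- as.logical(d$flag)
  class(d) <- c("cadence_series", "data.frame")
  d
}

#' Write / read a cohort CSV (missing values as empty fields)
#'
#' @param table A `cohort_table`.
#' @param path File path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, na.strings = "")
  if ("stratum" %in% names(d)) {
    d$stratum <- factor(d$stratum, levels = .severity_levels, ordered = TRUE)
  }
  if ("site_tech" %in% names(d)) d$site_tech <- factor(d$site_tech)
  class(d) <- c("cohort_table", "data.frame")
  d
}
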