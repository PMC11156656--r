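# Stable file schemas. CSV dialect is fixed: UTF-8, comma separator, "."
# decimal, mandatory header row, missing values written blank — so outputs
# never drift with the locale.

write_csv_strict <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_strict <- function(path, required, label = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", label, paste(miss, collapse = ", ")))
  df
}

#' Write / read a residue table CSV
#'
#' Columns: `sample_id`, `pesticide`, `concentration_ug_per_kg` (blank for
#' non-detects), `detected` (0/1).
#'
#' @param records a residue table data frame.
#' @param path file path.
#' @return `read_residue_csv()` returns the residue table; the writer
#'   returns the path invisibly.
#' @export
write_residue_csv <- function(records, path) {
  check_residue_table(records)
  write_csv_strict(records, path)
}

#' @rdname write_residue_csv
#' @export
read_residue_csv <- function(path) {
  df <- read_csv_strict(path, c("sample_id", "pesticide",
                                "concentration_ug_per_kg", "detected"))
  df$detected <- as.integer(df$detected)
  check_residue_table(df)
  class(df) <- c("residue_table", "data.frame")
  df
}

#' Write / read a calibration series CSV
#'
#' Columns: `level_ug_per_kg`, `analyte_area`, `is_area`, `medium`.
#'
#' @param series a [calibration_series()].
#' @param path file path.
#' @return `read_calibration_csv()` returns a `calibration_series` (the
#'   file must contain a single medium); the writer returns the path.
#' @export
write_calibration_csv <- function(series, path) {
  stopifnot(inherits(series, "calibration_series"))
  df <- data.frame(level_ug_per_kg = series$nominal_concentration,
                   analyte_area = series$analyte_area,
                   is_area = series$is_area,
                   medium = attr(series, "medium"))
  write_csv_strict(df, path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- read_csv_strict(path, c("level_ug_per_kg", "analyte_area", "is_area",
                                "medium"))
  med <- unique(df$medium)
  if (length(med) != 1)
    stop(basename(path), ": expected a single medium, found ",
         paste(med, collapse = ", "))
  calibration_series(df$level_ug_per_kg, df$analyte_area, df$is_area,
                     medium = med)
}

#' Write / read a spike-replicate CSV
#'
#' Columns: `day`, `replicate`, `measured_ug_per_kg`, `spike_level_ug_per_kg`.
#'
#' @param spikes a [spike_set()].
#' @param path file path.
#' @return `read_spike_csv()` returns a `spike_set` (single spike level per
#'   file); the writer returns the path.
#' @export
write_spike_csv <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_set"))
  df <- data.frame(day = spikes$day,
                   replicate = stats::ave(seq_len(nrow(spikes)), spikes$day,
                                          FUN = seq_along),
                   measured_ug_per_kg = spikes$measured,
                   spike_level_ug_per_kg = attr(spikes, "spike_level"))
  write_csv_strict(df, path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  df <- read_csv_strict(path, c("day", "replicate", "measured_ug_per_kg",
                                "spike_level_ug_per_kg"))
  lev <- unique(df$spike_level_ug_per_kg)
  if (length(lev) != 1)
    stop(basename(path), ": expected a single spike level")
  spike_set(lev, df$day, df$measured_ug_per_kg)
}

#' Write / read a blank-signal CSV
#'
#' Columns: `replicate`, `signal`.
#'
#' @param blanks a [blank_set()].
#' @param path file path.
#' @return `read_blank_csv()` returns a `blank_set`; the writer the path.
#' @export
write_blank_csv <- function(blanks, path) {
  stopifnot(inherits(blanks, "blank_set"))
  df <- data.frame(replicate = seq_along(blanks$signals),
                   signal = blanks$signals)
  write_csv_strict(df, path)
}

#' @rdname write_blank_csv
#' @export
read_blank_csv <- function(path) {
  df <- read_csv_strict(path, c("replicate", "signal"))
  blank_set(df$signal)
}
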