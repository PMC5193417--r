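# Readers, writers and validated in-memory series/tables.
#
# Conventions: all instants are naive local wall-clock stored as POSIXct in
# the "UTC" zone (loggers record local time; no DST adjustment is applied --
# a documented limitation). Logger CSVs are comma-separated UTF-8 with
# ISO-8601 timestamps, columns `timestamp, value`, one series per file.

#' Construct a validated hive-weight series
#'
#' A weight series is the raw record of one hive-scale logger: strictly
#' increasing timestamps, masses in kg, and a nominal sampling step
#' (15 min for the scale loggers used in the field trials this package
#' targets). Gaps -- inter-sample intervals longer than 1.5 x the nominal
#' step -- are annotated, never filled: they propagate to downstream window
#' validity checks.
#'
#' @param hive_id Character scalar identifying the hive.
#' @param time POSIXct (or ISO-8601 character) sample instants, local clock.
#' @param value Numeric masses in kg; must be finite and positive.
#' @param nominal_step Nominal sampling interval in minutes (default 15).
#' @return An object of class `hb_series` (subclass `hb_weight_series`):
#'   a list with `hive_id`, `time`, `value`, `nominal_step`, `kind`, and
#'   `gap_after`, a logical flagging samples followed by a gap.
#' @seealso [temp_series()], [read_logger_csv()]
#' @export
weight_series <- function(hive_id, time, value, nominal_step = 15) {
  new_series(hive_id, time, value, nominal_step, kind = "weight")
}

#' Construct a validated internal hive-temperature series
#'
#' Same contract as [weight_series()] but for in-hive temperature sensors
#' (nominal 30-min sampling); values must lie in the plausible range
#' \[-20, 60\] degrees C.
#'
#' @inheritParams weight_series
#' @param value Numeric temperatures in degrees C.
#' @param nominal_step Nominal sampling interval in minutes (default 30).
#' @return An `hb_series` of kind `"temperature"`.
#' @export
temp_series <- function(hive_id, time, value, nominal_step = 30) {
  new_series(hive_id, time, value, nominal_step, kind = "temperature")
}

new_series <- function(hive_id, time, value, nominal_step, kind) {
  stopifnot(length(hive_id) == 1L, is.numeric(value))
  time <- as_instant(time)
  if (length(time) != length(value))
    stopf("time (%d) and value (%d) lengths differ", length(time), length(value))
  if (anyNA(time)) stopf("unparseable timestamp at row %d", which(is.na(time))[1])
  if (!all(is.finite(value)))
    stopf("non-finite value at row %d", which(!is.finite(value))[1])
  d <- diff(as.numeric(time))
  if (any(d == 0))
    stopf("duplicated timestamp: %s",
          format(time[which(d == 0)[1] + 1L], "%Y-%m-%d %H:%M:%S"))
  if (any(d < 0)) stopf("timestamps not increasing at row %d", which(d < 0)[1] + 1L)
  if (!is.numeric(nominal_step) || nominal_step <= 0) stopf("nominal_step must be > 0")
  if (kind == "weight" && any(value <= 0))
    stopf("non-positive mass at row %d", which(value <= 0)[1])
  if (kind == "temperature" && any(value < -20 | value > 60))
    stopf("temperature outside [-20, 60] C at row %d",
          which(value < -20 | value > 60)[1])
  gap_after <- c(d > 1.5 * nominal_step * 60, FALSE)
  structure(
    list(hive_id = as.character(hive_id), time = time, value = as.numeric(value),
         nominal_step = nominal_step, kind = kind, gap_after = gap_after),
    class = c(paste0("hb_", kind, "_series"), "hb_series"))
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("<%s series> hive %s: %d samples, %s to %s, step %g min, %d gap(s)\n",
              x$kind, x$hive_id, length(x$value),
              format(x$time[1]), format(x$time[length(x$time)]),
              x$nominal_step, sum(x$gap_after)))
  invisible(x)
}

#' @export
length.hb_series <- function(x) length(x$value)

#' @export
as.data.frame.hb_series <- function(x, ...) {
  data.frame(timestamp = format(x$time, "%Y-%m-%dT%H:%M:%S"), value = x$value)
}

#' Number of annotated gaps in a series
#' @param series An `hb_series`.
#' @return Integer count of inter-sample gaps (> 1.5 x nominal step).
#' @export
n_gaps <- function(series) sum(series$gap_after)

#' Read a logger CSV into a validated series
#'
#' Expects a header row naming `timestamp` and `value` columns (extra
#' columns ignored). Rows out of order are sorted with a warning and the
#' number of moved rows recorded in attribute `reordered`; duplicated
#' timestamps are an error naming the duplicate. The nominal step, if not
#' given, is inferred as the median inter-sample interval. Ingest never
#' modifies values: only ordering and gap annotation.
#'
#' @param path CSV file path.
#' @param kind `"weight"` or `"temperature"`.
#' @param hive_id Hive identifier; defaults to the file name without extension.
#' @param nominal_step Minutes; `NULL` to infer.
#' @return An `hb_series`.
#' @export
read_logger_csv <- function(path, kind = c("weight", "temperature"),
                            hive_id = NULL, nominal_step = NULL) {
  kind <- match.arg(kind)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "value")
  if (!all(need %in% names(df)))
    stopf("%s: header must name columns 'timestamp' and 'value'", path)
  tm <- as_instant(df$timestamp)
  if (anyNA(tm))
    stopf("%s: unparseable timestamp '%s' at data row %d",
          path, df$timestamp[which(is.na(tm))[1]], which(is.na(tm))[1])
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val))
    stopf("%s: non-numeric value '%s' at data row %d",
          path, df$value[which(is.na(val))[1]], which(is.na(val))[1])
  if (anyDuplicated(tm))
    stopf("%s: duplicated timestamp: %s", path,
          format(tm[duplicated(tm)][1], "%Y-%m-%d %H:%M:%S"))
  reordered <- 0L
  if (is.unsorted(tm)) {
    o <- order(tm)
    reordered <- sum(o != seq_along(o))
    warnf("%s: %d out-of-order rows sorted", path, reordered)
    tm <- tm[o]; val <- val[o]
  }
  if (is.null(nominal_step))
    nominal_step <- stats::median(diff(as.numeric(tm))) / 60
  hive_id <- hive_id %||% sub("\\.[^.]*$", "", basename(path))
  out <- new_series(hive_id, tm, val, nominal_step, kind)
  attr(out, "reordered") <- reordered
  out
}

#' Read a long-format inspection table
#'
#' Long CSV `hive_id, date, metric, frame_index, value`. Recognised metrics
#' include `frame_weight_kg`, `brood_area_cm2`, `brood_hexagons`,
#' `frame_spaces`, `varroa_board_count`, `varroa_board_days`,
#' `varroa_wash_mites`, `varroa_wash_bees`. Frame spaces are validated as
#' half-integers in \[0, 10\] (the field scoring scale); all counts and
#' areas must be non-negative.
#'
#' @param path CSV file path.
#' @return A data.frame of class `hb_inspections`.
#' @export
read_inspections <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("hive_id", "date", "metric", "frame_index", "value")
  if (!all(need %in% names(df)))
    stopf("%s: inspection CSV needs columns %s", path, paste(need, collapse = ", "))
  df$date <- as.Date(df$date)
  fs <- df$metric == "frame_spaces"
  if (any(fs) && !all(is_half_step(df$value[fs])))
    stopf("frame_spaces must be half-integers in [0, 10]")
  ct <- df$metric %in% c("brood_area_cm2", "brood_hexagons", "varroa_board_count",
                         "varroa_wash_mites", "varroa_wash_bees")
  if (any(ct & (!is.finite(df$value) | df$value < 0)))
    stopf("negative or non-finite count/area in inspection table")
  class(df) <- c("hb_inspections", "data.frame")
  df
}

#' Read a feeding-schedule table
#'
#' CSV `hive_id, date, mass_kg, conc_ppb, unconsumed_kg` (last column
#' optional / may be NA). Masses must be non-negative and unconsumed syrup
#' cannot exceed the amount offered.
#'
#' @param path CSV file path.
#' @return A data.frame of class `hb_schedule`.
#' @export
read_feeding_schedule <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("hive_id", "date", "mass_kg", "conc_ppb")
  if (!all(need %in% names(df)))
    stopf("%s: schedule CSV needs columns %s", path, paste(need, collapse = ", "))
  if (!"unconsumed_kg" %in% names(df)) df$unconsumed_kg <- rep(NA_real_, nrow(df))
  df$date <- as.Date(df$date)
  feeding_schedule(df)
}

#' Validate a feeding-schedule data.frame
#'
#' @param df Data.frame with `hive_id, date, mass_kg, conc_ppb` and
#'   optionally `unconsumed_kg`.
#' @return The validated data.frame, class `hb_schedule`.
#' @export
feeding_schedule <- function(df) {
  if (!"unconsumed_kg" %in% names(df)) df$unconsumed_kg <- rep(NA_real_, nrow(df))
  if (any(df$mass_kg < 0, na.rm = TRUE)) stopf("syrup masses must be >= 0")
  if (any(df$conc_ppb < 0, na.rm = TRUE)) stopf("concentrations must be >= 0")
  bad <- !is.na(df$unconsumed_kg) & df$unconsumed_kg > df$mass_kg + 1e-9
  if (any(bad)) stopf("unconsumed syrup exceeds amount offered (row %d)", which(bad)[1])
  class(df) <- c("hb_schedule", "data.frame")
  df
}

#' Construct a treatment design
#'
#' Maps each hive to exactly one treatment group (imidacloprid ppb in syrup,
#' coumaphos ppm in patty/syrup).
#'
#' @param site Site label.
#' @param hive_id Character vector of hive identifiers (no duplicates).
#' @param imidacloprid_ppb Numeric dose per hive.
#' @param coumaphos_ppm Numeric dose per hive (default 0).
#' @return A data.frame of class `hb_design` with a `group` label column.
#' @export
treatment_design <- function(site, hive_id, imidacloprid_ppb, coumaphos_ppm = 0) {
  if (anyDuplicated(hive_id))
    stopf("hive assigned more than one group: %s", hive_id[duplicated(hive_id)][1])
  df <- data.frame(site = site, hive_id = as.character(hive_id),
                   imidacloprid_ppb = imidacloprid_ppb,
                   coumaphos_ppm = coumaphos_ppm,
                   stringsAsFactors = FALSE)
  df$group <- ifelse(df$coumaphos_ppm > 0,
                     sprintf("imi%g_cou%g", df$imidacloprid_ppb, df$coumaphos_ppm),
                     sprintf("imi%g", df$imidacloprid_ppb))
  class(df) <- c("hb_design", "data.frame")
  df
}

#' Write result tables to a directory
#'
#' Each element of `results` (a named list of data.frames, or of objects
#' with an `as.data.frame` method) is written as `<name>.csv` with
#' deterministic file names; outputs round-trip through `read.csv`.
#'
#' @param results Named list of tabular results.
#' @param out_dir Output directory (created if missing).
#' @return A manifest data.frame (`name`, `file`, `rows`), one row per file.
#' @export
write_report_tables <- function(results, out_dir) {
  stopifnot(is.list(results))
  if (length(results) && (is.null(names(results)) || any(names(results) == "")))
    stopf("results must be a named list")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory %s", out_dir)
  manifest <- data.frame(name = character(), file = character(),
                         rows = integer(), stringsAsFactors = FALSE)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    file <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(df, file, row.names = FALSE)
    manifest <- rbind(manifest, data.frame(name = nm, file = file, rows = nrow(df),
                                           stringsAsFactors = FALSE))
  }
  manifest
}
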