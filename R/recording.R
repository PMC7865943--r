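#' Construct a sensor recording
#'
#' A `sensor_recording` holds one subject's labeled 10-channel time series
#' in physical units: airbag pressure (kPa), triaxial acceleration (g),
#' triaxial angular rate (dps) and the three Euler angles (degrees),
#' sampled at 20 Hz by default.  Labels are per-sample activity codes.
#'
#' @param values numeric matrix `[n_samples x 10]`, columns in
#'   [har_channels()] order (a data.frame is coerced).
#' @param labels character vector of per-sample activity codes from
#'   [har_activities()], or `"UNLABELED"`.
#' @param subject_id subject identifier string.
#' @param sample_rate sampling rate in Hz (default 20).
#' @return object of class `sensor_recording`.
#' @export
sensor_recording <- function(values, labels, subject_id = "S1",
                             sample_rate = 20) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != 10L)
    stop("a recording must have exactly 10 channels, got ", ncol(values),
         call. = FALSE)
  if (nrow(values) != length(labels))
    stop("values has ", nrow(values), " rows but labels has length ",
         length(labels), call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0", call. = FALSE)
  labels <- as.character(labels)
  valid <- c(har_activities(), UNLABELED)
  if (!all(labels %in% valid)) {
    bad <- unique(labels[!labels %in% valid])
    stop("unknown activity label(s): ", paste(bad, collapse = ", "),
         "; valid codes: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  if (any(values[, 1L] < 0))
    stop("pressure channel must be non-negative (kPa)", call. = FALSE)
  colnames(values) <- har_channels()
  structure(
    list(subject_id = as.character(subject_id),
         sample_rate = sample_rate,
         channels = har_channels(),
         values = values,
         labels = labels),
    class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat("<sensor_recording> subject", x$subject_id, "-", nrow(x$values),
      "samples @", x$sample_rate, "Hz\n")
  tab <- table(x$labels)
  cat("  labels:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Read a recording from delimited text
#'
#' Reads a CSV with a header naming the 10 channel columns plus a label
#' column.  When the schema marks the pressure column as raw volts the
#' values are converted to kPa with [voltage_to_pressure()].
#'
#' @param path path to a CSV file.
#' @param schema list with elements `sample_rate` (Hz), `pressure_unit`
#'   (`"kPa"` or `"volts"`), `columns` (named map from canonical channel
#'   names to file column names; defaults to identity), `label` (label
#'   column name, default `"label"`), and `subject_id` (defaults to the
#'   file name without extension).
#' @return a [sensor_recording()].
#' @export
read_recording <- function(path, schema = list()) {
  schema <- utils::modifyList(
    list(sample_rate = 20, pressure_unit = "kPa", columns = NULL,
         label = "label", subject_id = NULL),
    schema)
  cols <- schema$columns
  if (is.null(cols)) cols <- stats::setNames(har_channels(), har_channels())
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c(unname(cols), schema$label)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- df[, unname(cols), drop = FALSE]
  for (j in seq_along(raw)) {
    v <- raw[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn) & !anyNA(v)) {
        row <- which(is.na(vn))[1L]
        stop("non-numeric value in column '", names(raw)[j],
             "' at data row ", row, call. = FALSE)
      }
      raw[[j]] <- vn
    }
    if (anyNA(raw[[j]])) {
      row <- which(is.na(raw[[j]]))[1L]
      stop("missing/unparseable value in column '", names(raw)[j],
           "' at data row ", row, call. = FALSE)
    }
  }
  values <- as.matrix(raw)
  if (identical(schema$pressure_unit, "volts"))
    values[, 1L] <- voltage_to_pressure(values[, 1L])
  subject <- schema$subject_id
  if (is.null(subject)) subject <- sub("\\.[^.]*$", "", basename(path))
  sensor_recording(values, df[[schema$label]], subject_id = subject,
                   sample_rate = schema$sample_rate)
}

#' Write a recording as delimited text
#'
#' Inverse of [read_recording()] for the canonical kPa schema.
#'
#' @param recording a [sensor_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "sensor_recording"))
  n <- nrow(recording$values)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$sample_rate,
                   recording$values,
                   label = recording$labels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
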