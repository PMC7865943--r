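#' Sliding-window segmentation
#'
#' Cuts a recording into fixed-length windows: 2 s at 20 Hz covers 40
#' samples, and with the default 50% overlap the window advances 20
#' samples (1 s) each step.  Windows are half-open `[start, start + w)`
#' with 0-based starts at multiples of the step.  A window is kept only
#' if all of its samples share one activity label (purity rule); the
#' number of dropped mixed-label windows is recorded in the result.
#'
#' @param recording a [sensor_recording()].
#' @param window_seconds window length in seconds (default 2).
#' @param overlap_fraction fraction of the window shared by consecutive
#'   windows, in `[0, 1)` (default 0.5).
#' @return object of class `har_segments`: list with `values` (array
#'   `[w x 10 x n_segments]`), `labels`, `starts` (0-based), `subject_id`,
#'   `window_samples`, `sample_rate`, `n_dropped`.
#' @export
segment_recording <- function(recording, window_seconds = 2,
                              overlap_fraction = 0.5) {
  stopifnot(inherits(recording, "sensor_recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  w <- as.integer(round(window_seconds * recording$sample_rate))
  step <- w * (1 - overlap_fraction)
  if (step != round(step))
    stop("window_samples * (1 - overlap_fraction) must be an integer",
         call. = FALSE)
  step <- as.integer(step)
  n <- nrow(recording$values)
  if (n < w) {
    warning("recording shorter than one window; returning empty segment set",
            call. = FALSE)
    starts <- integer(0)
  } else {
    starts <- seq.int(0L, n - w, by = step)
  }
  keep_label <- character(0)
  keep_start <- integer(0)
  for (s in starts) {
    lab <- recording$labels[(s + 1L):(s + w)]
    if (length(unique(lab)) == 1L && lab[1L] != UNLABELED) {
      keep_label <- c(keep_label, lab[1L])
      keep_start <- c(keep_start, s)
    }
  }
  vals <- array(0, dim = c(w, 10L, length(keep_start)),
                dimnames = list(NULL, har_channels(), NULL))
  for (i in seq_along(keep_start))
    vals[, , i] <- recording$values[(keep_start[i] + 1L):(keep_start[i] + w), ]
  structure(
    list(values = vals,
         labels = keep_label,
         starts = keep_start,
         subject_id = rep(recording$subject_id, length(keep_start)),
         window_samples = w,
         sample_rate = recording$sample_rate,
         n_dropped = length(starts) - length(keep_start)),
    class = "har_segments")
}

#' @export
print.har_segments <- function(x, ...) {
  cat("<har_segments>", length(x$labels), "windows of", x$window_samples,
      "samples (", x$n_dropped, "mixed-label windows dropped )\n")
  invisible(x)
}

#' Number of segments in a `har_segments` object
#' @param segments a `har_segments` object.
#' @export
n_segments <- function(segments) length(segments$labels)

# concatenate segment sets from several recordings (same window length)
#' Combine segment sets
#' @param ... `har_segments` objects with identical window length.
#' @return a single `har_segments` object.
#' @export
c_segments <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !inherits(sets[[1L]], "har_segments"))
    sets <- sets[[1L]]
  w <- unique(vapply(sets, function(s) s$window_samples, numeric(1)))
  if (length(w) != 1L)
    stop("segment sets have different window lengths", call. = FALSE)
  vals <- array(unlist(lapply(sets, function(s) s$values)),
                dim = c(w, 10L, sum(vapply(sets, n_segments, integer(1)))),
                dimnames = list(NULL, har_channels(), NULL))
  structure(
    list(values = vals,
         labels = unlist(lapply(sets, function(s) s$labels)),
         starts = unlist(lapply(sets, function(s) s$starts)),
         subject_id = unlist(lapply(sets, function(s) s$subject_id)),
         window_samples = w,
         sample_rate = sets[[1L]]$sample_rate,
         n_dropped = sum(vapply(sets, function(s) s$n_dropped, numeric(1)))),
    class = "har_segments")
}

# subset segments by index, preserving metadata
subset_segments <- function(segments, idx) {
  structure(
    list(values = segments$values[, , idx, drop = FALSE],
         labels = segments$labels[idx],
         starts = segments$starts[idx],
         subject_id = segments$subject_id[idx],
         window_samples = segments$window_samples,
         sample_rate = segments$sample_rate,
         n_dropped = segments$n_dropped),
    class = "har_segments")
}
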