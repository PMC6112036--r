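#' Construct a sensor stream
#'
#' A `sensor_stream` holds one device's timestamped multi-axis samples for a
#' single recording: integer millisecond timestamps since recording start and
#' one numeric value per channel per timestamp (acceleration in m/s^2 for the
#' wrist devices this package targets).
#'
#' @param timestamps integer vector, milliseconds since recording start,
#'   sorted ascending (unsorted input is sorted; duplicate timestamps keep the
#'   first occurrence).
#' @param values numeric matrix with one row per timestamp and one column per
#'   channel, or a vector for a single channel.
#' @param channels character vector of channel names, one per column.
#' @param recording_id,device identifying strings (e.g. device
#'   `"wrist_left"`).
#' @param sample_rate_hz nominal sampling rate in Hz (wristband 40, glasses
#'   50); sampling jitter is tolerated, operations that need a fixed rate
#'   resample first.
#' @return An object of class `sensor_stream`.
#' @seealso [read_sensor_csv()], [slice_stream()], [shift_stream()]
#' @export
sensor_stream <- function(timestamps, values, channels = NULL,
                          recording_id = "rec", device = "wrist_right",
                          sample_rate_hz = 40) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(channels)) {
    channels <- colnames(values)
    if (is.null(channels)) channels <- paste0("c", seq_len(ncol(values)))
  }
  if (length(channels) != ncol(values)) {
    stop("length(channels) must equal ncol(values)")
  }
  if (length(timestamps) != nrow(values)) {
    stop("length(timestamps) must equal nrow(values)")
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a positive number")
  }
  timestamps <- as.integer(round(timestamps))
  ord <- order(timestamps)
  timestamps <- timestamps[ord]
  values <- values[ord, , drop = FALSE]
  keep <- !duplicated(timestamps)
  timestamps <- timestamps[keep]
  values <- values[keep, , drop = FALSE]
  colnames(values) <- channels
  structure(
    list(recording_id = recording_id, device = device,
         sample_rate_hz = sample_rate_hz, timestamps = timestamps,
         channels = channels, values = values),
    class = "sensor_stream"
  )
}

#' @export
print.sensor_stream <- function(x, ...) {
  dur <- if (length(x$timestamps)) diff(range(x$timestamps)) else 0L
  cat(sprintf(
    "<sensor_stream> %s/%s: %d samples, %d channel(s) [%s], %.1f s @ %g Hz nominal\n",
    x$recording_id, x$device, length(x$timestamps), length(x$channels),
    paste(x$channels, collapse = ","), dur / 1000, x$sample_rate_hz))
  invisible(x)
}

n_samples <- function(stream) length(stream$timestamps)

stream_duration_ms <- function(stream) {
  if (!n_samples(stream)) return(0L)
  diff(range(stream$timestamps))
}

#' Label intervals
#'
#' Annotated activity spans. Intervals are half-open `[start_ms, end_ms)`
#' everywhere in the package so that abutting intervals do not overlap.
#'
#' @param start_ms,end_ms integer vectors, `start_ms < end_ms` elementwise.
#' @param label character vector of activity labels.
#' @param hand one of `"left"`, `"right"`, `"both"`, `"unknown"` per interval.
#' @return A `data.frame` with class `label_intervals`, sorted by `start_ms`.
#' @export
label_intervals <- function(start_ms, end_ms, label,
                            hand = rep("unknown", length(start_ms))) {
  start_ms <- as.integer(round(start_ms))
  end_ms <- as.integer(round(end_ms))
  label <- as.character(label)
  hand <- as.character(hand)
  bad <- which(start_ms >= end_ms)
  if (length(bad)) {
    stop(sprintf("label interval %d invalid: start_ms (%d) >= end_ms (%d)",
                 bad[1], start_ms[bad[1]], end_ms[bad[1]]))
  }
  ok_hand <- hand %in% c("left", "right", "both", "unknown")
  if (!all(ok_hand)) {
    stop(sprintf("invalid hand value '%s' (row %d)",
                 hand[which(!ok_hand)[1]], which(!ok_hand)[1]))
  }
  df <- data.frame(start_ms = start_ms, end_ms = end_ms, label = label,
                   hand = hand, stringsAsFactors = FALSE)
  df <- df[order(df$start_ms, df$end_ms), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("label_intervals", "data.frame")
  df
}

empty_labels <- function() {
  label_intervals(integer(0), integer(0), character(0), character(0))
}

#' Bundle streams and labels into a recording
#'
#' @param streams a single `sensor_stream` or a list of them; named by device
#'   when the names are missing.
#' @param labels a `label_intervals` table (may be empty).
#' @param recording_id identifier; defaults to the first stream's.
#' @param metadata free-form named list.
#' @return An object of class `recording`.
#' @export
recording <- function(streams, labels = empty_labels(),
                      recording_id = NULL, metadata = list()) {
  if (inherits(streams, "sensor_stream")) streams <- list(streams)
  stopifnot(length(streams) >= 1)
  for (s in streams) {
    if (!inherits(s, "sensor_stream")) stop("streams must be sensor_stream objects")
  }
  if (is.null(names(streams)) || any(!nzchar(names(streams)))) {
    names(streams) <- vapply(streams, function(s) s$device, character(1))
  }
  if (is.null(recording_id)) recording_id <- streams[[1]]$recording_id
  if (!inherits(labels, "label_intervals")) {
    labels <- label_intervals(labels$start_ms, labels$end_ms, labels$label,
                              if ("hand" %in% names(labels)) labels$hand
                              else rep("unknown", nrow(labels)))
  }
  structure(list(recording_id = recording_id, streams = streams,
                 labels = labels, metadata = metadata),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d stream(s) [%s], %d label(s)\n",
              x$recording_id, length(x$streams),
              paste(names(x$streams), collapse = ","), nrow(x$labels)))
  invisible(x)
}

#' Read a sensor stream from CSV
#'
#' Expects a header row with a `timestamp_ms` column (milliseconds) followed
#' by one or more numeric channel columns; channel order is preserved from the
#' header. Rows are sorted by timestamp and duplicate timestamps keep the
#' first occurrence.
#'
#' @param path CSV file path.
#' @param device,sample_rate_hz stream metadata, see [sensor_stream()].
#' @param recording_id recording identifier; defaults to the file base name.
#' @return A `sensor_stream`.
#' @export
read_sensor_csv <- function(path, device = "wrist_right", sample_rate_hz = 40,
                            recording_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"timestamp_ms" %in% names(df)) {
    stop(sprintf("format error: '%s' has no 'timestamp_ms' column", path))
  }
  chan_cols <- setdiff(names(df), "timestamp_ms")
  if (!length(chan_cols)) stop(sprintf("format error: '%s' has no channel columns", path))
  for (cc in c("timestamp_ms", chan_cols)) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      row <- if (length(bad)) bad[1] else which(is.na(as.numeric(v)))[1]
      stop(sprintf("parse error in '%s': non-numeric value in column '%s' at data row %d",
                   path, cc, row))
    }
  }
  if (is.null(recording_id)) {
    recording_id <- tools::file_path_sans_ext(basename(path))
  }
  sensor_stream(df$timestamp_ms, as.matrix(df[chan_cols]), channels = chan_cols,
                recording_id = recording_id, device = device,
                sample_rate_hz = sample_rate_hz)
}

#' Write a sensor stream to CSV
#'
#' Emits the same dialect [read_sensor_csv()] reads: comma-separated, header
#' `timestamp_ms,<channels...>`, `'.'` decimal separator, `\n` line endings.
#'
#' @param stream a `sensor_stream`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(stream, path) {
  df <- data.frame(timestamp_ms = stream$timestamps,
                   stream$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read label intervals from CSV
#'
#' Expects columns `start_ms,end_ms,label` and optionally `hand`; `hand`
#' defaults to `"unknown"`. Returned intervals are sorted by `start_ms`.
#'
#' @param path CSV file path.
#' @return A `label_intervals` table.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_ms", "end_ms", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("format error: '%s' lacks column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  bad <- which(df$start_ms >= df$end_ms)
  if (length(bad)) {
    stop(sprintf("validation error in '%s': start_ms >= end_ms at data row %d",
                 path, bad[1]))
  }
  hand <- if ("hand" %in% names(df)) df$hand else rep("unknown", nrow(df))
  hand[is.na(hand) | !nzchar(hand)] <- "unknown"
  label_intervals(df$start_ms, df$end_ms, df$label, hand)
}

#' Write label intervals to CSV
#'
#' @param labels a `label_intervals` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  df <- as.data.frame(labels)[c("start_ms", "end_ms", "label", "hand")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Shift a stream in time
#'
#' Adds a constant offset to every timestamp (the programmatic counterpart of
#' aligning devices whose clocks differ by a constant). Timestamps may become
#' negative; trimming is left to the caller.
#'
#' @param stream a `sensor_stream`.
#' @param offset_ms integer offset in milliseconds (may be negative).
#' @return The shifted `sensor_stream`.
#' @export
shift_stream <- function(stream, offset_ms) {
  stream$timestamps <- as.integer(stream$timestamps + round(offset_ms))
  stream
}

#' Slice a stream to a half-open time window
#'
#' Keeps samples with `start_ms <= t < end_ms`; an empty result is allowed.
#'
#' @param stream a `sensor_stream`.
#' @param start_ms,end_ms window bounds, `start_ms < end_ms`.
#' @return The sliced `sensor_stream` (timestamps remain absolute).
#' @export
slice_stream <- function(stream, start_ms, end_ms) {
  if (start_ms >= end_ms) {
    stop(sprintf("validation error: slice start (%s) must be < end (%s)",
                 format(start_ms), format(end_ms)))
  }
  keep <- stream$timestamps >= start_ms & stream$timestamps < end_ms
  stream$timestamps <- stream$timestamps[keep]
  stream$values <- stream$values[keep, , drop = FALSE]
  stream
}
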