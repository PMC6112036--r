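#' Construct a template
#'
#' A template is an annotated, preprocessed signal segment used as a query
#' pattern: its label, the hand it was performed with, the recording and
#' time span it came from, the preprocessed sample matrix, and a fingerprint
#' of the preprocessing configuration so it can only be matched against
#' identically preprocessed streams. Zeroline (idle) templates carry the
#' reserved label `"__zeroline__"`.
#'
#' @param label activity label.
#' @param sequence numeric matrix of preprocessed samples (rows = time).
#' @param span_ms length-2 integer vector `(start, end)`, half-open, in the
#'   source recording's time base.
#' @param source_recording recording id the span came from.
#' @param hand `"left"`, `"right"`, `"both"` or `"unknown"`.
#' @param fingerprint [preprocess_fingerprint()] of the configuration used.
#' @param id unique template id; generated from source and span if omitted.
#' @param timestamps optional millisecond timestamps of the sequence rows.
#' @return An object of class `activity_template`.
#' @export
activity_template <- function(label, sequence, span_ms, source_recording,
                              hand = "unknown", fingerprint = "",
                              id = NULL, timestamps = NULL) {
  sequence <- as.matrix(sequence)
  storage.mode(sequence) <- "double"
  if (!nrow(sequence)) stop("validation error: template sequence is empty")
  if (is.null(id)) {
    id <- sprintf("%s_%d_%d_%s", source_recording, span_ms[1], span_ms[2], hand)
  }
  structure(list(id = id, label = label, hand = hand,
                 source_recording = source_recording,
                 span_ms = as.integer(span_ms), sequence = sequence,
                 timestamps = timestamps,
                 preprocess_fingerprint = fingerprint),
            class = "activity_template")
}

#' @export
print.activity_template <- function(x, ...) {
  cat(sprintf("<activity_template> %s '%s' (%s hand) [%d,%d) ms, %d samples x %d ch\n",
              x$id, x$label, x$hand, x$span_ms[1], x$span_ms[2],
              nrow(x$sequence), ncol(x$sequence)))
  invisible(x)
}

ZEROLINE_LABEL <- "__zeroline__"

is_zeroline_template <- function(tpl) identical(tpl$label, ZEROLINE_LABEL)

# Pick the stream of a recording matching a label's hand; hand "unknown" or
# "both" falls back to default_device, then to the first stream.
stream_for_hand <- function(rec, hand, default_device = NULL) {
  devs <- names(rec$streams)
  pick <- switch(hand,
                 left = grep("left", devs, value = TRUE),
                 right = grep("right", devs, value = TRUE),
                 character(0))
  if (!length(pick) && !is.null(default_device) && default_device %in% devs) {
    pick <- default_device
  }
  if (!length(pick)) pick <- devs[1]
  rec$streams[[pick[1]]]
}

#' Extract activity templates from a labeled recording
#'
#' One template per label interval (optionally restricted to a set of
#' labels): the stream for the label's hand is preprocessed under `cfg` and
#' sliced to the interval. When `leading_ms` is set, only the initial
#' portion of each interval is used -- matching only the initial arm
#' movement of an activity generalizes better across semantically different
#' activities sharing that motion.
#'
#' @param rec a [recording()] with labels.
#' @param cfg a [preprocess_config()].
#' @param labels_filter optional character vector; only intervals with these
#'   labels yield templates.
#' @param leading_ms optional truncation: the slice becomes
#'   `[start, start + leading_ms)`.
#' @param default_device stream to use for hand `"unknown"`/`"both"`.
#' @return A list of [activity_template()] objects (possibly empty).
#' @export
extract_templates <- function(rec, cfg, labels_filter = NULL,
                              leading_ms = NULL, default_device = NULL) {
  stopifnot(inherits(rec, "recording"), inherits(cfg, "preprocess_config"))
  labs <- rec$labels
  if (!is.null(labels_filter)) labs <- labs[labs$label %in% labels_filter, , drop = FALSE]
  fp <- preprocess_fingerprint(cfg)
  out <- vector("list", nrow(labs))
  for (i in seq_len(nrow(labs))) {
    row <- labs[i, ]
    stream <- stream_for_hand(rec, row$hand, default_device)
    end <- if (is.null(leading_ms)) row$end_ms else
      min(row$end_ms, row$start_ms + leading_ms)
    if (row$start_ms < min(stream$timestamps) ||
        row$end_ms > max(stream$timestamps) + 1000 / stream$sample_rate_hz) {
      stop(sprintf("label interval [%d,%d) '%s' lies outside stream '%s'",
                   row$start_ms, row$end_ms, row$label, stream$device))
    }
    pre <- apply_preprocess(stream, cfg)
    sl <- slice_stream(pre, row$start_ms, end)
    if (!n_samples(sl)) {
      stop(sprintf("empty slice for label interval [%d,%d) '%s'",
                   row$start_ms, row$end_ms, row$label))
    }
    out[[i]] <- activity_template(row$label, sl$values, c(row$start_ms, end),
                                  rec$recording_id, hand = row$hand,
                                  fingerprint = fp, timestamps = sl$timestamps)
  }
  out
}

#' Detect zeroline (idle) intervals
#'
#' A zeroline is a period of no movement -- recordings start and end with
#' one by protocol. Detection: the rolling standard deviation of the
#' acceleration magnitude over a 1 s window must stay below
#' `mag_std_threshold` for at least `min_len_ms`.
#'
#' @param stream a `sensor_stream`; 3-channel streams are reduced to
#'   magnitude first, single-channel streams are used as-is.
#' @param min_len_ms minimum interval length (default 2000 ms).
#' @param mag_std_threshold rolling-sd threshold in m/s^2 (default 0.05).
#' @return A `label_intervals` table (label `"__zeroline__"`), possibly
#'   empty, sorted by start; intervals are maximal and pairwise disjoint.
#' @export
detect_zeroline <- function(stream, min_len_ms = 2000, mag_std_threshold = 0.05) {
  mag <- if (length(stream$channels) == 3) reduce_to_magnitude(stream) else stream
  x <- mag$values[, 1]
  n <- length(x)
  win <- max(2L, round(stream$sample_rate_hz))  # ~1 s of samples
  if (n < win) return(empty_labels())
  rsd <- zoo::rollapply(x, width = win, FUN = stats::sd, fill = NA,
                        align = "center", partial = TRUE)
  quiet <- !is.na(rsd) & rsd < mag_std_threshold
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  t0 <- integer(0); t1 <- integer(0)
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    a <- mag$timestamps[starts[k]]
    b <- mag$timestamps[ends[k]] + round(1000 / stream$sample_rate_hz)
    if (b - a >= min_len_ms) { t0 <- c(t0, a); t1 <- c(t1, b) }
  }
  if (!length(t0)) return(empty_labels())
  label_intervals(t0, t1, rep(ZEROLINE_LABEL, length(t0)))
}

#' Extract a zeroline (idle) template
#'
#' Builds the null template used by zeroline candidate filtering: a segment
#' of no movement, either from an explicitly annotated span or from the
#' first interval [detect_zeroline()] finds. So that idle and activity
#' templates are comparable in span, the segment is truncated to
#' `target_len_ms` (callers typically pass the median activity-template
#' duration).
#'
#' @param rec a [recording()].
#' @param cfg a [preprocess_config()].
#' @param span optional 1-row `label_intervals` (or list with
#'   `start_ms`/`end_ms`) naming the idle span.
#' @param target_len_ms optional truncation length in ms.
#' @param device stream to draw from (default: first stream).
#' @return An [activity_template()] with label `"__zeroline__"`.
#' @export
extract_zeroline_template <- function(rec, cfg, span = NULL,
                                      target_len_ms = NULL, device = NULL) {
  stream <- if (is.null(device)) rec$streams[[1]] else rec$streams[[device]]
  if (is.null(span)) {
    found <- detect_zeroline(stream)
    if (!nrow(found)) {
      stop("no idle (zeroline) interval detected; annotate one manually and pass `span`")
    }
    span <- found[1, ]
  }
  start <- span$start_ms[1]
  end <- span$end_ms[1]
  if (!is.finite(start) || !is.finite(end) || start >= end) {
    stop("validation error: zeroline span must have start < end")
  }
  if (!is.null(target_len_ms)) end <- min(end, start + target_len_ms)
  pre <- apply_preprocess(stream, cfg)
  sl <- slice_stream(pre, start, end)
  if (!n_samples(sl)) stop("empty zeroline slice")
  activity_template(ZEROLINE_LABEL, sl$values, c(start, end),
                    rec$recording_id, hand = "unknown",
                    fingerprint = preprocess_fingerprint(cfg),
                    timestamps = sl$timestamps)
}

#' Write a template store to a directory
#'
#' One `templates.json` metadata file (id, label, hand, source, span,
#' fingerprint) plus one sensor CSV per template holding the preprocessed
#' sequence.
#'
#' @param templates list of [activity_template()]s.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_template_store <- function(templates, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- lapply(templates, function(tp) {
    list(id = tp$id, label = tp$label, hand = tp$hand,
         source_recording = tp$source_recording,
         span_ms = tp$span_ms, fingerprint = tp$preprocess_fingerprint,
         file = paste0(tp$id, ".csv"))
  })
  jsonlite::write_json(meta, file.path(dir, "templates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (tp in templates) {
    ts <- if (is.null(tp$timestamps)) seq_len(nrow(tp$sequence)) - 1L else tp$timestamps
    st <- sensor_stream(ts, tp$sequence, recording_id = tp$source_recording)
    write_sensor_csv(st, file.path(dir, paste0(tp$id, ".csv")))
  }
  invisible(dir)
}

#' Read a template store written by [write_template_store()]
#'
#' @param dir store directory.
#' @return A list of [activity_template()]s.
#' @export
read_template_store <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "templates.json"),
                              simplifyVector = FALSE)
  lapply(meta, function(m) {
    st <- read_sensor_csv(file.path(dir, m$file))
    activity_template(m$label, st$values, unlist(m$span_ms),
                      m$source_recording, hand = m$hand,
                      fingerprint = m$fingerprint, id = m$id,
                      timestamps = st$timestamps)
  })
}
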