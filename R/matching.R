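#' Candidate selection configuration
#'
#' How the pool of subsequence matches is reduced to at most `k` label
#' candidates. `"delta"` is greedy temporal exclusion: candidates are taken
#' in order of ascending distance and one is accepted only if it starts at
#' least `delta_ms` from every already-accepted candidate (activities are
#' assumed not to occur within a shorter period; 2 s default). `"zeroline"`
#' keeps only candidates that beat an idle template's distance at the same
#' position, then takes the k smallest.
#'
#' @param method `"delta"` or `"zeroline"`.
#' @param k maximum number of candidates (>= 1; typical sweeps use 5--20).
#' @param delta_ms exclusion radius in ms for `"delta"` (default 2000).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(method = c("delta", "zeroline"), k = 10,
                             delta_ms = 2000) {
  method <- match.arg(method)
  if (!is.numeric(k) || k < 1) stop("k must be a positive integer")
  if (!is.numeric(delta_ms) || delta_ms <= 0) stop("delta_ms must be > 0")
  structure(list(method = method, k = as.integer(k),
                 delta_ms = as.integer(delta_ms)),
            class = "selection_config")
}

empty_candidates <- function() {
  data.frame(start_ms = integer(0), end_ms = integer(0), distance = numeric(0),
             template_label = character(0), template_id = character(0),
             start_index = integer(0), end_index = integer(0),
             stringsAsFactors = FALSE)
}

#' Match one template against a stream
#'
#' Preprocesses the stream under `cfg` (which must be the configuration the
#' template was extracted with -- fingerprints are compared), runs
#' [best_subsequence_matches()], and converts sample-index spans to
#' half-open millisecond spans via the stream's timestamps.
#'
#' @param template an [activity_template()].
#' @param stream a raw `sensor_stream`.
#' @param cfg the [preprocess_config()] the template was built with.
#' @param normalize normalize match distances by warping-path length.
#' @return A candidate `data.frame` (`start_ms`, `end_ms`, `distance`,
#'   `template_label`, `template_id`, `start_index`, `end_index`), sorted by
#'   distance ascending.
#' @export
match_template <- function(template, stream, cfg, normalize = TRUE) {
  fp <- preprocess_fingerprint(cfg)
  if (nzchar(template$preprocess_fingerprint) &&
      !identical(template$preprocess_fingerprint, fp)) {
    stop(sprintf(
      "config error: template '%s' was preprocessed with '%s' but cfg is '%s'",
      template$id, template$preprocess_fingerprint, fp))
  }
  pre <- apply_preprocess(stream, cfg)
  if (n_samples(pre) < 2) stop("stream too short to match against")
  m <- best_subsequence_matches(template$sequence, pre$values, normalize = normalize)
  step <- round(1000 / pre$sample_rate_hz)
  out <- data.frame(start_ms = pre$timestamps[m$start_index],
                    end_ms = pre$timestamps[m$end_index] + step,
                    distance = m$distance,
                    template_label = rep(template$label, nrow(m)),
                    template_id = rep(template$id, nrow(m)),
                    start_index = m$start_index,
                    end_index = m$end_index,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Zeroline top-k candidate selection
#'
#' Keeps only the candidates whose match distance is strictly smaller than
#' the idle ("zeroline") template's subsequence distance ending at the same
#' series position -- the assumption being that away from real activity the
#' idle template matches at least as well -- then returns the k smallest by
#' distance (ties: earlier start first). The result may be empty: when the
#' zeroline beats every activity template everywhere, no candidate survives.
#'
#' @param candidates candidate `data.frame` from [match_template()]
#'   (possibly pooled across templates), with `end_index` positions into the
#'   same preprocessed stream as `zeroline_last_row`.
#' @param zeroline_last_row numeric vector: per-position zeroline
#'   subsequence distance over the same stream (normalize it the same way
#'   the candidates were).
#' @param k maximum candidates to return.
#' @return A candidate `data.frame` with at most `k` rows.
#' @export
select_topk_zeroline <- function(candidates, zeroline_last_row, k) {
  if (!nrow(candidates)) return(candidates)
  keep <- candidates$distance < zeroline_last_row[candidates$end_index]
  surv <- candidates[keep, , drop = FALSE]
  surv <- surv[order(surv$distance, surv$start_ms), , drop = FALSE]
  out <- utils::head(surv, k)
  rownames(out) <- NULL
  out
}

#' Delta-exclusion top-k candidate selection
#'
#' Greedy temporal non-maximum suppression: iterate candidates in ascending
#' distance (ties by start time) and accept one only if its start lies at
#' least `delta_ms` from every already-accepted start; stop after k.
#'
#' @param candidates candidate `data.frame`.
#' @param k maximum candidates to return.
#' @param delta_ms exclusion radius in ms (default 2000).
#' @return A candidate `data.frame` with at most `k` rows whose pairwise
#'   start separations are all `>= delta_ms`.
#' @export
select_topk_delta <- function(candidates, k, delta_ms = 2000) {
  if (!nrow(candidates)) return(candidates)
  ord <- candidates[order(candidates$distance, candidates$start_ms), , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(ord))) {
    if (length(accepted) >= k) break
    if (all(abs(ord$start_ms[i] - ord$start_ms[accepted]) >= delta_ms)) {
      accepted <- c(accepted, i)
    }
  }
  out <- ord[accepted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sliding fixed-length matcher (single-activity recordings)
#'
#' For recordings known to contain (at least) one instance of the activity,
#' the template slides over the stream at fixed length: at each stride
#' offset the full DTW distance between the template and the equally long
#' window is computed, and the single minimal-distance window is returned.
#' The returned span has the template's duration by construction -- the
#' known accuracy limitation of this matcher.
#'
#' @param template an [activity_template()].
#' @param stream a raw `sensor_stream`.
#' @param cfg the matching [preprocess_config()].
#' @param stride_samples window step in samples (default 5, i.e. 125 ms at
#'   40 Hz; 1 = exhaustive).
#' @param normalize report the path-length-normalized distance.
#' @return A one-row candidate `data.frame`.
#' @export
sliding_fixed_match <- function(template, stream, cfg, stride_samples = 5,
                                normalize = TRUE) {
  fp <- preprocess_fingerprint(cfg)
  if (nzchar(template$preprocess_fingerprint) &&
      !identical(template$preprocess_fingerprint, fp)) {
    stop("config error: template/config fingerprint mismatch")
  }
  pre <- apply_preprocess(stream, cfg)
  m <- nrow(template$sequence)
  n <- n_samples(pre)
  if (n < m) stop("validation error: stream shorter than template")
  offsets <- seq.int(1L, n - m + 1L, by = max(1L, as.integer(stride_samples)))
  best <- NULL
  best_d <- Inf
  for (o in offsets) {
    win <- pre$values[o:(o + m - 1L), , drop = FALSE]
    r <- .dtw_full_cpp(template$sequence, win, TRUE)
    d <- if (normalize) r$distance / r$path_length else r$distance
    if (d < best_d) { best_d <- d; best <- o }
  }
  step <- round(1000 / pre$sample_rate_hz)
  data.frame(start_ms = pre$timestamps[best],
             end_ms = pre$timestamps[best + m - 1L] + step,
             distance = best_d,
             template_label = template$label, template_id = template$id,
             start_index = best, end_index = best + m - 1L,
             stringsAsFactors = FALSE)
}

#' Most self-consistent subset of per-template best matches
#'
#' Given each template's single best match in a recording, exhaustively
#' scores every size-k subset by the mean pairwise temporal overlap
#' ([interval_overlap()]) among its members and returns the argmax subset
#' (ties: lexicographically smallest index set). Picking the subset that
#' agrees most with itself suppresses templates that matched in the wrong
#' place; empirically k = 6 of 8--10 templates works well for
#' single-activity picking recordings.
#'
#' @param per_template_best candidate `data.frame`, one row per template.
#' @param k subset size, `2 <= k <= nrow(per_template_best)`.
#' @return The selected rows of `per_template_best`.
#' @export
best_subset <- function(per_template_best, k) {
  n <- nrow(per_template_best)
  if (k < 2) stop("validation error: k must be >= 2")
  if (n < k) stop("validation error: fewer candidates than k")
  if (choose(n, k) > 1e6) {
    stop(sprintf("refusing exhaustive search: C(%d,%d) = %.3g subsets > 1e6",
                 n, k, choose(n, k)))
  }
  ov <- matrix(0, n, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      ov[a, b] <- ov[b, a] <- interval_overlap(
        c(per_template_best$start_ms[a], per_template_best$end_ms[a]),
        c(per_template_best$start_ms[b], per_template_best$end_ms[b]))
    }
  }
  subs <- utils::combn(n, k)
  best_score <- -Inf
  best_idx <- NULL
  for (s in seq_len(ncol(subs))) {
    idx <- subs[, s]
    score <- mean(ov[idx, idx][upper.tri(matrix(0, k, k))])
    if (score > best_score) { best_score <- score; best_idx <- idx }
  }
  out <- per_template_best[best_idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recommend label candidates for a recording
#'
#' The end-to-end matcher: every activity template in the store is matched
#' against the recording's stream, all candidates are pooled, and the
#' configured selection rule is applied once to the pool. For
#' `method = "zeroline"` the store must contain a `"__zeroline__"` template
#' (see [extract_zeroline_template()]); its per-position subsequence
#' distance over the same preprocessed stream provides the filter baseline.
#'
#' @param rec a [recording()].
#' @param templates list of [activity_template()]s (activity templates plus,
#'   for zeroline selection, one idle template).
#' @param cfg the [preprocess_config()] the templates were built with.
#' @param sel a [selection_config()].
#' @param device which stream of the recording to match (default: first).
#' @param normalize normalize DTW distances by warping-path length.
#' @return A candidate `data.frame` with at most `sel$k` rows, sorted by
#'   `start_ms`.
#' @export
recommend <- function(rec, templates, cfg, sel, device = NULL,
                      normalize = TRUE) {
  stopifnot(inherits(rec, "recording"), inherits(sel, "selection_config"))
  zl <- Filter(is_zeroline_template, templates)
  act <- Filter(Negate(is_zeroline_template), templates)
  if (!length(act)) stop("config error: no activity templates supplied")
  stream <- if (is.null(device)) rec$streams[[1]] else rec$streams[[device]]
  pooled <- do.call(rbind, lapply(act, match_template, stream = stream,
                                  cfg = cfg, normalize = normalize))
  out <- if (sel$method == "delta") {
    select_topk_delta(pooled, sel$k, sel$delta_ms)
  } else {
    if (!length(zl)) {
      stop("config error: zeroline selection needs a '__zeroline__' template")
    }
    pre <- apply_preprocess(stream, cfg)
    sub <- dtw_subsequence(zl[[1]]$sequence, pre$values)
    zrow <- if (normalize) sub$last_row / sub$path_length else sub$last_row
    select_topk_zeroline(pooled, zrow, sel$k)
  }
  out <- out[order(out$start_ms, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read candidate lists
#'
#' Candidates are exchanged as CSV with columns
#' `start_ms,end_ms,distance,template_label,template_id`, importable back as
#' provisional label intervals for an annotation round-trip.
#'
#' @param candidates candidate `data.frame`.
#' @param path CSV path.
#' @return `path` invisibly for the writer; for [candidates_as_labels()] a
#'   `label_intervals` table whose labels are the source template labels.
#' @export
write_candidates_csv <- function(candidates, path) {
  cols <- c("start_ms", "end_ms", "distance", "template_label", "template_id")
  utils::write.csv(candidates[cols], path, row.names = FALSE, quote = FALSE,
                   eol = "\n")
  invisible(path)
}

#' @rdname write_candidates_csv
#' @export
candidates_as_labels <- function(candidates) {
  label_intervals(candidates$start_ms, candidates$end_ms,
                  candidates$template_label)
}
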