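#' Temporal overlap of two half-open spans
#'
#' Default definition is the Jaccard index |a∩b| / |a∪b| (symmetric,
#' bounded in `[0,1]`, 1 iff the spans are equal, 0 when disjoint). The
#' alternative `"truth"` mode reports intersection over the second span's
#' duration, which some event-spotting evaluations use.
#'
#' @param a,b length-2 numeric vectors `(start, end)`, half-open, `start <
#'   end`.
#' @param mode `"jaccard"` (default) or `"truth"`.
#' @return A number in `[0,1]`.
#' @export
interval_overlap <- function(a, b, mode = c("jaccard", "truth")) {
  mode <- match.arg(mode)
  if (a[1] >= a[2] || b[1] >= b[2]) stop("validation error: spans need start < end")
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  if (mode == "truth") return(inter / (b[2] - b[1]))
  # union of two possibly disjoint spans: total covered length
  uni <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  inter / uni
}

#' Start and duration offsets between a prediction and the truth
#'
#' @param pred,truth length-2 spans in ms.
#' @return Named numeric vector `(delta_start_s, delta_duration_s)`:
#'   absolute start offset and absolute duration difference, in seconds.
#' @export
boundary_deltas <- function(pred, truth) {
  c(delta_start_s = abs(pred[1] - truth[1]) / 1000,
    delta_duration_s = abs((pred[2] - pred[1]) - (truth[2] - truth[1])) / 1000)
}

#' Distance from a candidate to the nearest label
#'
#' 0 when the candidate span overlaps any label; otherwise the smallest gap
#' in seconds between the candidate and its nearest label span. This is the
#' per-candidate error the configuration sweeps aggregate (min / median /
#' max).
#'
#' @param candidate one-row candidate `data.frame` or length-2 span in ms.
#' @param labels a non-empty `label_intervals` table.
#' @return Distance in seconds (>= 0).
#' @export
candidate_label_distance <- function(candidate, labels) {
  if (!nrow(labels)) stop("validation error: empty label list")
  span <- if (is.data.frame(candidate)) {
    c(candidate$start_ms[1], candidate$end_ms[1])
  } else as.numeric(candidate)
  gaps <- vapply(seq_len(nrow(labels)), function(i) {
    ls <- labels$start_ms[i]; le <- labels$end_ms[i]
    if (span[1] < le && ls < span[2]) return(0)          # overlap
    max(ls - span[2], span[1] - le) / 1000
  }, numeric(1))
  min(gaps)
}

#' Fraction of labels recovered by the candidate list
#'
#' A ground-truth label counts as found (a true positive) when at least one
#' candidate span overlaps it.
#'
#' @param candidates candidate `data.frame` (possibly empty).
#' @param labels non-empty `label_intervals`.
#' @return Recall in `[0,1]`.
#' @export
recall_at_k <- function(candidates, labels) {
  if (!nrow(labels)) stop("validation error: empty label list")
  if (!nrow(candidates)) return(0)
  hit <- vapply(seq_len(nrow(labels)), function(i) {
    any(candidates$start_ms < labels$end_ms[i] &
          labels$start_ms[i] < candidates$end_ms)
  }, logical(1))
  mean(hit)
}

#' ROC curve over scored windows
#'
#' Standard threshold sweep: windows are sorted by decreasing score (a
#' higher score should indicate activity; use the negated match distance)
#' and each distinct score is a threshold yielding one (FPR, TPR) point.
#' Both coordinates are non-decreasing along the sweep; the curve starts at
#' (0,0) and ends at (1,1).
#'
#' @param scores numeric vector, one per window.
#' @param is_positive logical vector: does the window overlap a true label?
#' @return An object of class `roc_points`: `data.frame` with `threshold`,
#'   `fpr`, `tpr`, plus an `auc` attribute (trapezoidal).
#' @export
roc_curve <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  is_positive <- as.logical(is_positive)
  if (!any(is_positive) || all(is_positive)) {
    stop("validation error: need at least one positive and one negative window")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- is_positive[ord]
  P <- sum(y); N <- sum(!y)
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(rev(s))  # keep the last index of each tied score block
  keep <- rev(last)
  df <- data.frame(threshold = s[keep], fpr = fp[keep] / N, tpr = tp[keep] / P)
  df <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), df)
  rownames(df) <- NULL
  auc <- sum(diff(df$fpr) * (utils::head(df$tpr, -1) + utils::tail(df$tpr, -1)) / 2)
  attr(df, "auc") <- auc
  class(df) <- c("roc_points", "data.frame")
  df
}

#' Score fixed windows of a recording for ROC analysis
#'
#' Discretizes the recording timeline into fixed windows (default 1 s); a
#' window is positive iff it overlaps a ground-truth label, and its score is
#' the negated minimal subsequence match distance observed at any series
#' position inside the window, minimized across the supplied templates. A
#' position's distance is the best distance of any match whose warped span
#' covers it (subsequence DTW anchors distances at match *ends*; spreading
#' them over the matched span scores the whole activity, not just its last
#' sample).
#'
#' @param rec a [recording()].
#' @param templates activity templates.
#' @param cfg the matching [preprocess_config()].
#' @param window_ms window length in ms (default 1000).
#' @param device stream to score.
#' @param normalize normalize distances by warping-path length.
#' @return A `data.frame` with `window_start_ms`, `score`, `is_positive`.
#' @export
score_windows <- function(rec, templates, cfg, window_ms = 1000,
                          device = NULL, normalize = TRUE) {
  stream <- if (is.null(device)) rec$streams[[1]] else rec$streams[[device]]
  pre <- apply_preprocess(stream, cfg)
  act <- Filter(Negate(is_zeroline_template), templates)
  n <- n_samples(pre)
  best <- rep(Inf, n)
  for (tp in act) {
    sub <- dtw_subsequence(tp$sequence, pre$values)
    d <- if (normalize) sub$last_row / sub$path_length else sub$last_row
    for (j in seq_len(n)) {
      span <- sub$start_index[j]:j
      hit <- d[j] < best[span]
      if (any(hit)) best[span[hit]] <- d[j]
    }
  }
  t0 <- pre$timestamps[1]
  win <- floor((pre$timestamps - t0) / window_ms)
  starts <- t0 + unique(win) * window_ms
  score <- -vapply(unique(win), function(w) min(best[win == w]), numeric(1))
  pos <- vapply(starts, function(ws) {
    any(rec$labels$start_ms < ws + window_ms & ws < rec$labels$end_ms)
  }, logical(1))
  data.frame(window_start_ms = starts, score = score, is_positive = pos)
}

#' Sweep template count and k
#'
#' For every combination of template count and k: subsample that many
#' activity templates (seeded), run [recommend()] on every recording, and
#' aggregate the candidate-to-label distances into min / median / max
#' seconds plus mean recall. This is the grid used to ask how many labeled
#' examples an annotator must provide -- typically very few templates with a
#' moderate k already localize the activities.
#'
#' @param recordings list of [recording()]s with ground-truth labels.
#' @param templates pool of activity templates (a zeroline template may be
#'   included for `sel_method = "zeroline"`).
#' @param template_counts,k_values integer vectors to sweep.
#' @param cfg a [preprocess_config()].
#' @param sel_method `"delta"` or `"zeroline"`.
#' @param delta_ms exclusion radius for delta selection.
#' @param seed RNG seed for the template subsampling.
#' @return A `data.frame` with one row per grid cell: `n_templates`, `k`,
#'   `min_s`, `median_s`, `max_s`, `recall`.
#' @export
sweep_grid <- function(recordings, templates, template_counts, k_values,
                       cfg, sel_method = "delta", delta_ms = 2000, seed = 1) {
  act <- Filter(Negate(is_zeroline_template), templates)
  zl <- Filter(is_zeroline_template, templates)
  if (max(template_counts) > length(act)) {
    stop("validation error: template_counts exceeds available templates")
  }
  grid <- expand.grid(n_templates = template_counts, k = k_values)
  res <- withr::with_seed(seed, {
    lapply(seq_len(nrow(grid)), function(g) {
      nt <- grid$n_templates[g]; k <- grid$k[g]
      use <- c(sample(act, nt), zl)
      sel <- selection_config(sel_method, k = k, delta_ms = delta_ms)
      dists <- numeric(0); recs <- numeric(0)
      for (rec in recordings) {
        cand <- recommend(rec, use, cfg, sel)
        if (nrow(cand)) {
          dists <- c(dists, vapply(seq_len(nrow(cand)), function(i)
            candidate_label_distance(cand[i, ], rec$labels), numeric(1)))
        }
        recs <- c(recs, recall_at_k(cand, rec$labels))
      }
      data.frame(n_templates = nt, k = k,
                 min_s = if (length(dists)) min(dists) else NA_real_,
                 median_s = if (length(dists)) stats::median(dists) else NA_real_,
                 max_s = if (length(dists)) max(dists) else NA_real_,
                 recall = mean(recs))
    })
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Leave-one-recording-out evaluation
#'
#' For each recording, templates are extracted from all *other* recordings
#' (subsampled to `n_templates`, seeded), [recommend()] is run on the
#' held-out one, and recall plus candidate-to-label distance statistics are
#' reported per fold with aggregate means.
#'
#' @param recordings at least two labeled [recording()]s.
#' @param cfg a [preprocess_config()].
#' @param sel a [selection_config()].
#' @param n_templates number of templates drawn per fold (`NULL` = all).
#' @param leading_ms optional truncation passed to [extract_templates()].
#' @param seed RNG seed for the per-fold template subsampling.
#' @param device stream to match.
#' @return A list with `folds` (data.frame: `held_out`, `recall`, `min_s`,
#'   `median_s`, `max_s`, `n_candidates`) and `aggregate` (named means).
#' @export
leave_one_out <- function(recordings, cfg, sel, n_templates = NULL,
                          leading_ms = NULL, seed = 1, device = NULL) {
  if (length(recordings) < 2) {
    stop("validation error: leave-one-out needs >= 2 recordings")
  }
  folds <- withr::with_seed(seed, {
    lapply(seq_along(recordings), function(i) {
      held <- recordings[[i]]
      pool <- unlist(lapply(recordings[-i], extract_templates, cfg = cfg,
                            leading_ms = leading_ms), recursive = FALSE)
      if (!is.null(n_templates) && n_templates < length(pool)) {
        pool <- sample(pool, n_templates)
      }
      if (sel$method == "zeroline") {
        med <- stats::median(vapply(pool, function(tp) diff(tp$span_ms), numeric(1)))
        pool <- c(pool, list(extract_zeroline_template(held, cfg,
                                                       target_len_ms = med)))
      }
      cand <- recommend(held, pool, cfg, sel, device = device)
      dists <- if (nrow(cand)) vapply(seq_len(nrow(cand)), function(j)
        candidate_label_distance(cand[j, ], held$labels), numeric(1)) else numeric(0)
      data.frame(held_out = held$recording_id,
                 recall = recall_at_k(cand, held$labels),
                 min_s = if (length(dists)) min(dists) else NA_real_,
                 median_s = if (length(dists)) stats::median(dists) else NA_real_,
                 max_s = if (length(dists)) max(dists) else NA_real_,
                 n_candidates = nrow(cand),
                 stringsAsFactors = FALSE)
    })
  })
  df <- do.call(rbind, folds)
  rownames(df) <- NULL
  list(folds = df,
       aggregate = c(recall = mean(df$recall),
                     median_s = stats::median(df$median_s, na.rm = TRUE),
                     min_s = min(df$min_s, na.rm = TRUE),
                     max_s = max(df$max_s, na.rm = TRUE)))
}
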