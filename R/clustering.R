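#' Cluster templates by motion similarity
#'
#' Complex activities (meal preparation and the like) are grouped by what
#' the arm actually does, not by their semantic labels: each template is
#' summarized as a sequence of windowed features (spectral energy + median
#' absolute deviation per channel, see [windowed_features()]), pairwise DTW
#' distances between those feature sequences are computed, and agglomerative
#' hierarchical clustering is run on the distance matrix.
#'
#' @param templates at least two [activity_template()]s with sampled
#'   timestamps.
#' @param window_len_ms,hop_ms feature windowing. Clustering uses shorter,
#'   densely overlapping windows (400/100 ms) than generic feature
#'   extraction: templates are only a few seconds long, and a handful of
#'   coarse windows washes out the temporal structure that separates
#'   motion classes.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param sample_rate_hz rate of the template sequences (needed to window
#'   them); default 40.
#' @param use_features cluster on feature sequences (default); `FALSE`
#'   clusters on the raw template signals instead.
#' @param standardize z-score each feature dimension across all templates'
#'   windows before DTW (default `TRUE`): energy is quadratic in amplitude
#'   and MAD linear, so unstandardized distances are dominated by within-
#'   class amplitude variation rather than motion character.
#' @return An object of class `template_dendrogram`: list with `merge`,
#'   `height`, `labels` (template ids), `template_labels` (activity labels),
#'   `linkage`, `hclust` (the underlying [stats::hclust()] object) and
#'   `dist` (the DTW distance matrix).
#' @export
cluster_templates <- function(templates, window_len_ms = 400, hop_ms = 100,
                              linkage = c("average", "complete", "single"),
                              sample_rate_hz = 40, use_features = TRUE,
                              standardize = TRUE) {
  linkage <- match.arg(linkage)
  if (length(templates) < 2) stop("validation error: need >= 2 templates")
  seqs <- lapply(templates, function(tp) {
    if (!use_features) return(tp$sequence)
    ts <- if (is.null(tp$timestamps)) {
      round(seq(0, by = 1000 / sample_rate_hz, length.out = nrow(tp$sequence)))
    } else tp$timestamps
    st <- sensor_stream(ts, tp$sequence, recording_id = tp$source_recording,
                        sample_rate_hz = sample_rate_hz)
    fs <- tryCatch(windowed_features(st, window_len_ms, hop_ms),
                   error = function(e) NULL)
    if (is.null(fs) || !nrow(fs$features)) {
      stop(sprintf("template '%s' too short for one %d ms feature window",
                   tp$id, window_len_ms))
    }
    fs$features
  })
  if (use_features && standardize) {
    all <- do.call(rbind, seqs)
    mu <- colMeans(all)
    sdv <- apply(all, 2, stats::sd)
    sdv[sdv == 0] <- 1
    seqs <- lapply(seqs, function(f) sweep(sweep(f, 2, mu), 2, sdv, "/"))
  }
  names(seqs) <- vapply(templates, `[[`, character(1), "id")
  D <- pairwise_dtw_matrix(seqs)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 template_labels = vapply(templates, `[[`, character(1), "label"),
                 linkage = linkage, hclust = hc, dist = D),
            class = "template_dendrogram")
}

#' @export
print.template_dendrogram <- function(x, ...) {
  cat(sprintf("<template_dendrogram> %d leaves, %s linkage, heights [%.4g, %.4g]\n",
              length(x$labels), x$linkage, min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a template dendrogram into flat clusters
#'
#' @param dend a [cluster_templates()] result.
#' @param n_clusters number of groups, `1 <= n_clusters <=` number of
#'   leaves.
#' @return Named integer vector mapping template id to cluster id; cluster
#'   ids are numbered by their smallest member leaf index (cluster 1
#'   contains leaf 1).
#' @export
cut_dendrogram <- function(dend, n_clusters) {
  n <- length(dend$labels)
  if (n_clusters < 1 || n_clusters > n) {
    stop(sprintf("validation error: n_clusters must lie in [1, %d]", n))
  }
  raw <- stats::cutree(dend$hclust, k = n_clusters)
  # renumber so cluster ids are ordered by smallest member leaf index
  first_idx <- vapply(split(seq_along(raw), raw), min, numeric(1))
  new_id <- rank(first_idx)
  out <- as.integer(new_id[as.character(raw)])
  names(out) <- dend$labels
  out
}

#' Export a dendrogram as a Newick tree
#'
#' Rooted Newick with branch lengths derived from merge heights: a leaf's
#' branch is its parent's merge height, an internal node's branch is the
#' height difference to its parent. Parseable by standard tree readers
#' (e.g. `ape::read.tree`).
#'
#' @param dend a [cluster_templates()] result.
#' @param digits branch-length precision.
#' @return A single Newick string (terminated by `;`).
#' @export
export_newick <- function(dend, digits = 6) {
  merge <- dend$merge
  height <- dend$height
  labs <- dend$labels
  fmt <- function(x) sprintf("%.*g", digits, x)
  # child height: 0 for leaves, own merge height for internal nodes
  node_str <- function(child, parent_h) {
    if (child < 0) {
      sprintf("%s:%s", labs[-child], fmt(parent_h))
    } else {
      h <- height[child]
      sprintf("(%s,%s):%s", node_str(merge[child, 1], h),
              node_str(merge[child, 2], h), fmt(parent_h - h))
    }
  }
  root <- nrow(merge)
  h <- height[root]
  sprintf("(%s,%s);", node_str(merge[root, 1], h), node_str(merge[root, 2], h))
}
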