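#' @useDynLib actispot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

as_seq_matrix <- function(x, arg = "sequence") {
  if (inherits(x, "sensor_stream")) x <- x$values
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!nrow(x)) stop(sprintf("validation error: %s is empty", arg))
  x
}

check_same_dim <- function(a, b) {
  if (ncol(a) != ncol(b)) {
    stop(sprintf("validation error: dimensionality mismatch (%d vs %d channels)",
                 ncol(a), ncol(b)))
  }
}

#' Full dynamic time warping distance
#'
#' Minimal accumulated Euclidean cost over all monotone warping paths from
#' the first sample pair to the last, with the classic recursion
#' `d(i,j) = cost(i,j) + min(d(i,j-1), d(i-1,j), d(i-1,j-1))` (steps
#' \{(1,0),(0,1),(1,1)\}, no step weights, no band). DTW tolerates execution
#' speed differences, which is why it is used to match activity templates of
#' different lengths. Backtracking ties are broken deterministically:
#' diagonal, then vertical `(i-1,j)`, then horizontal `(i,j-1)`.
#'
#' @param query,reference numeric vectors (univariate) or matrices with one
#'   row per time point and one column per channel; equal channel counts.
#' @return An object of class `dtw_result`: list with `distance`, `path`
#'   (2-column matrix of 1-based (query, reference) indices),
#'   `normalized_distance` (`distance / path length`) and `path_length`.
#' @export
dtw_full <- function(query, reference) {
  q <- as_seq_matrix(query, "query")
  r <- as_seq_matrix(reference, "reference")
  check_same_dim(q, r)
  res <- .dtw_full_cpp(q, r, TRUE)
  structure(list(distance = res$distance,
                 path = res$path,
                 path_length = res$path_length,
                 normalized_distance = res$distance / res$path_length),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance %.6g (normalized %.6g), path length %d\n",
              x$distance, x$normalized_distance, x$path_length))
  invisible(x)
}

#' Subsequence dynamic time warping
#'
#' Matches a short template anywhere inside a long series: the first
#' template row of the accumulated-cost matrix is initialized to the local
#' cost at every series position (free start), so `last_row[j]` is the
#' minimal cost of matching the *whole* template ending at series position
#' `j`. Start positions and warping-path lengths of the optimal paths are
#' returned alongside, allowing O(1) recovery of each matched span.
#'
#' @param template,series numeric vectors or matrices (rows = time points);
#'   equal channel counts. The series may be shorter than the template.
#' @return A list with `last_row` (length `nrow(series)`), `start_index`
#'   (1-based optimal start per end position) and `path_length`.
#' @export
dtw_subsequence <- function(template, series) {
  tm <- as_seq_matrix(template, "template")
  se <- as_seq_matrix(series, "series")
  check_same_dim(tm, se)
  .dtw_subseq_cpp(tm, se)
}

#' Candidate matches of a template inside a series
#'
#' Runs [dtw_subsequence()] and extracts one candidate per local minimum of
#' the accumulated-cost `last_row` (strict local minima; plateaus resolve to
#' their leftmost index). Each candidate carries the matched span (inclusive
#' start/end indices into the series) and its distance, normalized by
#' warping-path length when `normalize` is set so that distances are
#' comparable across templates of different lengths.
#'
#' @inheritParams dtw_subsequence
#' @param normalize divide each match distance by its warping-path length
#'   (default `TRUE`).
#' @return A `data.frame` with columns `start_index`, `end_index`,
#'   `distance`, `raw_distance`, `path_length`, sorted by `distance`
#'   ascending (ties by `start_index`).
#' @export
best_subsequence_matches <- function(template, series, normalize = TRUE) {
  sub <- dtw_subsequence(template, series)
  lr <- sub$last_row
  n <- length(lr)
  ends <- local_minima(lr)
  dist <- if (normalize) lr[ends] / sub$path_length[ends] else lr[ends]
  out <- data.frame(start_index = sub$start_index[ends],
                    end_index = ends,
                    distance = dist,
                    raw_distance = lr[ends],
                    path_length = sub$path_length[ends])
  out <- out[order(out$distance, out$start_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Indices of local minima of a numeric vector; plateaus yield their leftmost
# index; boundary points count when no neighbor on the existing side is
# smaller.
local_minima <- function(x) {
  n <- length(x)
  if (n == 1L) return(1L)
  # left condition: start of a descent (or of the vector)
  left_ok <- c(TRUE, x[-1] < x[-n])
  # right condition: nearest strictly different value to the right is larger
  # (or there is none)
  nxt_diff <- rep(Inf, n)
  for (i in rev(seq_len(n - 1))) {
    nxt_diff[i] <- if (x[i + 1] != x[i]) x[i + 1] else nxt_diff[i + 1]
  }
  which(left_ok & x < nxt_diff)
}

#' Pairwise DTW distance matrix
#'
#' Entry (a,b) is the path-length-normalized [dtw_full()] distance between
#' sequences a and b; the diagonal is 0 and the matrix is symmetric. Feeds
#' agglomerative clustering of templates.
#'
#' @param sequences list of numeric vectors or matrices with a common
#'   channel count.
#' @param normalize use the path-length-normalized distance (default
#'   `TRUE`); unnormalized distances reproduce the length bias where short
#'   sequences look systematically closer.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
pairwise_dtw_matrix <- function(sequences, normalize = TRUE) {
  if (length(sequences) < 2) stop("validation error: need at least 2 sequences")
  mats <- lapply(sequences, as_seq_matrix)
  for (m in mats[-1]) check_same_dim(mats[[1]], m)
  n <- length(mats)
  D <- matrix(0, n, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      res <- dtw_full(mats[[a]], mats[[b]])
      D[a, b] <- D[b, a] <- if (normalize) res$normalized_distance else res$distance
    }
  }
  nm <- names(sequences)
  if (!is.null(nm)) dimnames(D) <- list(nm, nm)
  D
}
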