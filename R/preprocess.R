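#' Preprocessing configuration
#'
#' Collects the signal-representation choices that are swept when tuning the
#' matcher: which acceleration component to match on (`raw`, the low-pass
#' `gravity` component, or the residual `linear` component), whether to
#' reduce the three axes to a single magnitude channel, the smoothing factor
#' of the gravity low-pass filter, and an optional uniform resampling rate.
#'
#' @param acceleration_type `"raw"`, `"gravity"` or `"linear"`.
#' @param reduce_dimensions if `TRUE`, collapse x,y,z to the Euclidean vector
#'   magnitude after the component selection.
#' @param lowpass_alpha smoothing factor in (0,1) of the first-order
#'   exponential gravity filter; ignored for `acceleration_type = "raw"`.
#'   0.8 is the conventional wearable gravity-filter constant.
#' @param resample_hz optional positive rate; when set, streams are resampled
#'   to this uniform rate before anything else.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(acceleration_type = c("raw", "gravity", "linear"),
                              reduce_dimensions = FALSE,
                              lowpass_alpha = 0.8,
                              resample_hz = NULL) {
  acceleration_type <- match.arg(acceleration_type)
  if (!is.logical(reduce_dimensions) || length(reduce_dimensions) != 1) {
    stop("reduce_dimensions must be a single logical")
  }
  if (acceleration_type != "raw" &&
      (!is.numeric(lowpass_alpha) || lowpass_alpha <= 0 || lowpass_alpha >= 1)) {
    stop("lowpass_alpha must lie strictly in (0,1)")
  }
  if (!is.null(resample_hz) && (!is.numeric(resample_hz) || resample_hz <= 0)) {
    stop("resample_hz must be a positive number or NULL")
  }
  structure(list(acceleration_type = acceleration_type,
                 reduce_dimensions = isTRUE(reduce_dimensions),
                 lowpass_alpha = lowpass_alpha,
                 resample_hz = resample_hz),
            class = "preprocess_config")
}

#' Fingerprint of a preprocessing configuration
#'
#' Deterministic string identifying a [preprocess_config()]; templates carry
#' it so a template extracted under one configuration cannot silently be
#' matched against a stream preprocessed under another.
#'
#' @param cfg a `preprocess_config`.
#' @return A single string.
#' @export
preprocess_fingerprint <- function(cfg) {
  stopifnot(inherits(cfg, "preprocess_config"))
  alpha <- if (cfg$acceleration_type == "raw") "-" else
    sprintf("%.10g", cfg$lowpass_alpha)
  rs <- if (is.null(cfg$resample_hz)) "-" else sprintf("%.10g", cfg$resample_hz)
  sprintf("at=%s|rd=%d|alpha=%s|rs=%s",
          cfg$acceleration_type, as.integer(cfg$reduce_dimensions), alpha, rs)
}

#' Resample a stream to a uniform rate
#'
#' Android-style sensor stacks push samples with jitter; windowed operations
#' and the FFT need a fixed grid. Output timestamps are
#' `first + round(k * 1000/rate_hz)` milliseconds for `k = 0, 1, ...` within
#' `[first, last]` of the input; values are linearly interpolated per channel.
#'
#' @param stream a `sensor_stream` with at least 2 samples.
#' @param rate_hz target rate in Hz.
#' @return A uniformly sampled `sensor_stream` with `sample_rate_hz = rate_hz`.
#' @export
resample_uniform <- function(stream, rate_hz) {
  if (n_samples(stream) < 2) {
    stop("validation error: resampling needs at least 2 samples")
  }
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  t0 <- stream$timestamps[1]
  t1 <- stream$timestamps[n_samples(stream)]
  step <- 1000 / rate_hz
  k <- 0:floor((t1 - t0) / step)
  grid <- as.integer(t0 + round(k * step))
  grid <- grid[grid <= t1]
  vals <- vapply(seq_along(stream$channels), function(j) {
    stats::approx(stream$timestamps, stream$values[, j], xout = grid,
                  method = "linear", rule = 1)$y
  }, numeric(length(grid)))
  if (length(grid) == 1L) vals <- matrix(vals, nrow = 1L)
  sensor_stream(grid, vals, channels = stream$channels,
                recording_id = stream$recording_id, device = stream$device,
                sample_rate_hz = rate_hz)
}

#' Split raw acceleration into gravity and linear components
#'
#' First-order exponential low-pass per channel:
#' `gravity[t] = alpha * gravity[t-1] + (1 - alpha) * raw[t]`, with
#' `gravity[1] = raw[1]`; the linear (motion) component is the residual
#' `raw - gravity`. Timestamps are preserved.
#'
#' @param stream a `sensor_stream` of raw acceleration.
#' @param alpha smoothing factor in (0,1); larger alpha = slower filter =
#'   smoother gravity estimate.
#' @return A list with `sensor_stream` elements `gravity` and `linear`.
#' @export
decompose_acceleration <- function(stream, alpha = 0.8) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("validation error: alpha must lie strictly in (0,1)")
  }
  n <- n_samples(stream)
  grav <- stream$values
  if (n > 1) {
    for (j in seq_len(ncol(grav))) {
      x <- stream$values[, j]
      # y[t] = (1-alpha) x[t] + alpha y[t-1], seeded so y[1] = x[1]
      grav[, j] <- as.numeric(stats::filter((1 - alpha) * x, alpha,
                                            method = "recursive",
                                            init = x[1] * 1))
      grav[1, j] <- x[1]
    }
  }
  gravity <- stream
  gravity$values <- grav
  linear <- stream
  linear$values <- stream$values - grav
  list(gravity = gravity, linear = linear)
}

#' Reduce a 3-axis stream to its vector magnitude
#'
#' Interprets each (x,y,z) sample as a vector and keeps only its Euclidean
#' length, discarding orientation information -- which often generalizes
#' better across wearers.
#'
#' @param stream a `sensor_stream` with exactly 3 channels.
#' @return A single-channel (`"mag"`) `sensor_stream`.
#' @export
reduce_to_magnitude <- function(stream) {
  if (length(stream$channels) != 3) {
    stop(sprintf("validation error: magnitude reduction needs 3 channels, got %d",
                 length(stream$channels)))
  }
  mag <- sqrt(rowSums(stream$values^2))
  sensor_stream(stream$timestamps, matrix(mag, ncol = 1), channels = "mag",
                recording_id = stream$recording_id, device = stream$device,
                sample_rate_hz = stream$sample_rate_hz)
}

#' Angles of the acceleration vector to the coordinate axes
#'
#' Per sample, the angle between the instantaneous acceleration vector and
#' each positive axis: `theta_a = acos(a / |v|)` in radians. An all-zero
#' sample is degenerate; its three angles are set to 0 and a warning is
#' raised.
#'
#' @param stream a `sensor_stream` with exactly 3 channels.
#' @return A `sensor_stream` with channels `theta_x`, `theta_y`, `theta_z`.
#' @export
axis_angles <- function(stream) {
  if (length(stream$channels) != 3) {
    stop("validation error: axis angles need exactly 3 channels")
  }
  mag <- sqrt(rowSums(stream$values^2))
  zero <- mag == 0
  if (any(zero)) warning(sprintf("%d all-zero sample(s): angles set to 0", sum(zero)))
  safe <- ifelse(zero, 1, mag)
  ang <- acos(pmin(pmax(stream$values / safe, -1), 1))
  ang[zero, ] <- 0
  sensor_stream(stream$timestamps, ang,
                channels = c("theta_x", "theta_y", "theta_z"),
                recording_id = stream$recording_id, device = stream$device,
                sample_rate_hz = stream$sample_rate_hz)
}

#' Unify left- and right-wrist streams into one vector stream
#'
#' For bilateral setups the activity is represented by a single vector per
#' time point: both streams are resampled to a common uniform rate, joined on
#' the intersection of their timestamp grids, and the right channels are
#' appended after the left ones (names prefixed by device side).
#'
#' @param left,right `sensor_stream`s covering overlapping time.
#' @param rate_hz common rate; defaults to the smaller of the two nominal
#'   rates.
#' @return A `sensor_stream` with `ncol(left) + ncol(right)` channels.
#' @export
unify_bilateral <- function(left, right, rate_hz = NULL) {
  if (is.null(rate_hz)) rate_hz <- min(left$sample_rate_hz, right$sample_rate_hz)
  lu <- resample_uniform(left, rate_hz)
  ru <- resample_uniform(right, rate_hz)
  common <- intersect(lu$timestamps, ru$timestamps)
  if (!length(common)) {
    stop("validation error: streams share no timestamps after resampling")
  }
  li <- match(common, lu$timestamps)
  ri <- match(common, ru$timestamps)
  vals <- cbind(lu$values[li, , drop = FALSE], ru$values[ri, , drop = FALSE])
  chans <- c(paste0("L_", lu$channels), paste0("R_", ru$channels))
  sensor_stream(common, vals, channels = chans,
                recording_id = left$recording_id, device = "bilateral",
                sample_rate_hz = rate_hz)
}

#' Windowed spectral-energy and dispersion features
#'
#' Complex activities are matched on short-window features rather than the
#' raw signal. Per window and channel two features are computed: the spectral
#' energy of the mean-removed window (sum of squared DFT magnitudes over the
#' non-DC bins, scaled to per-sample power, i.e. the window's biased
#' variance for a mean-removed signal -- `A^2/2` for a full-period sinusoid
#' of amplitude `A`) and the median absolute deviation
#' `median(|x - median(x)|)` (unscaled). The feature vector concatenates all
#' channels' energies then all channels' MADs. The trailing partial window is
#' dropped.
#'
#' @param stream a uniformly sampled `sensor_stream`.
#' @param window_len_ms,hop_ms window length and hop in ms; the window must
#'   contain at least 4 samples. Defaults: 32 samples at 40 Hz (800 ms) with
#'   50% overlap.
#' @return An object of class `feature_sequence`: list with
#'   `window_starts_ms`, `features` (matrix, one row per window),
#'   `window_len_ms`, `hop_ms`, `channels`.
#' @export
windowed_features <- function(stream, window_len_ms = 800, hop_ms = 400) {
  n <- n_samples(stream)
  if (n < 2) stop("validation error: need at least 2 samples")
  step_ms <- 1000 / stream$sample_rate_hz
  win_n <- floor(window_len_ms / step_ms)
  hop_n <- max(1L, floor(hop_ms / step_ms))
  if (win_n < 4) {
    stop(sprintf("validation error: window of %d ms holds %d sample(s) at %g Hz; need >= 4",
                 window_len_ms, win_n, stream$sample_rate_hz))
  }
  starts <- if (n >= win_n) seq.int(1L, n - win_n + 1L, by = hop_n) else integer(0)
  nc <- length(stream$channels)
  feats <- matrix(NA_real_, nrow = length(starts), ncol = 2L * nc)
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + win_n - 1L)
    en <- numeric(nc); md <- numeric(nc)
    for (j in seq_len(nc)) {
      x <- stream$values[idx, j]
      xc <- x - mean(x)
      sp <- Mod(stats::fft(xc))^2
      en[j] <- sum(sp[-1]) / win_n^2
      md[j] <- stats::mad(x, constant = 1)
    }
    feats[w, ] <- c(en, md)
  }
  colnames(feats) <- c(paste0("energy_", stream$channels),
                       paste0("mad_", stream$channels))
  structure(list(window_starts_ms = stream$timestamps[starts],
                 features = feats,
                 window_len_ms = as.integer(window_len_ms),
                 hop_ms = as.integer(hop_ms),
                 channels = stream$channels),
            class = "feature_sequence")
}

#' Apply a preprocessing configuration to a stream
#'
#' Composition order: optional uniform resampling, then the acceleration
#' component selection (`raw` passes through; `gravity`/`linear` take the
#' corresponding branch of [decompose_acceleration()]), then optional
#' magnitude reduction.
#'
#' @param stream a `sensor_stream`.
#' @param cfg a [preprocess_config()].
#' @return The preprocessed `sensor_stream`.
#' @export
apply_preprocess <- function(stream, cfg) {
  stopifnot(inherits(cfg, "preprocess_config"))
  out <- stream
  if (!is.null(cfg$resample_hz)) out <- resample_uniform(out, cfg$resample_hz)
  if (cfg$acceleration_type != "raw") {
    dec <- decompose_acceleration(out, cfg$lowpass_alpha)
    out <- dec[[cfg$acceleration_type]]
  }
  if (cfg$reduce_dimensions) out <- reduce_to_magnitude(out)
  out
}
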