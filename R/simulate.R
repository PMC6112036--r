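#' Synthetic recording configuration
#'
#' Describes the recordings the generator emulates: a wrist accelerometer
#' sampled nominally at 40 Hz, one to a few minutes long, idle ("zeroline")
#' padding at both ends, and a handful of short activity bursts per
#' recording. Activity motifs are class-specific smooth bursts (sums of
#' Gaussian-windowed sinusoids) whose execution speed and amplitude vary
#' per instance, which is exactly the variability DTW matching is meant to
#' absorb.
#'
#' @param seed integer RNG seed; everything downstream is reproducible from
#'   it.
#' @param sample_rate_hz sampling rate (default 40).
#' @param duration_s recording length in seconds (default 90; realistic
#'   recordings run 60--180 s).
#' @param n_activities planted activities per recording (default 3, at most
#'   4 in the emulated protocol; 0 gives a pure idle recording).
#' @param motif_classes list of motif specs, see [default_motif_classes()].
#' @param noise_sd white-noise standard deviation in m/s^2 (default 0.25).
#' @param idle_pad_s guaranteed idle padding at both ends in seconds
#'   (default 5).
#' @param warp_factor_range length-2 range of time-scaling factors applied
#'   per motif instance (default `c(0.8, 1.25)`).
#' @param min_gap_s minimum gap between activities (default 3 s, so a 2 s
#'   exclusion radius can isolate each one).
#' @param gravity gravity vector in m/s^2 (default `c(0, 0, 9.81)`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, sample_rate_hz = 40, duration_s = 90,
                       n_activities = 3, motif_classes = default_motif_classes(),
                       noise_sd = 0.25, idle_pad_s = 5,
                       warp_factor_range = c(0.8, 1.25), min_gap_s = 3,
                       gravity = c(0, 0, 9.81)) {
  max_dur <- max(vapply(motif_classes, function(m) m$duration_s[2], numeric(1)))
  need <- n_activities * (max_dur * warp_factor_range[2] + min_gap_s) +
    2 * idle_pad_s
  if (need > duration_s) {
    stop(sprintf("infeasible packing: %d activities need up to %.1f s but duration is %.1f s",
                 n_activities, need, duration_s))
  }
  structure(list(seed = as.integer(seed), sample_rate_hz = sample_rate_hz,
                 duration_s = duration_s, n_activities = n_activities,
                 motif_classes = motif_classes, noise_sd = noise_sd,
                 idle_pad_s = idle_pad_s,
                 warp_factor_range = warp_factor_range,
                 min_gap_s = min_gap_s, gravity = gravity),
            class = "sim_config")
}

#' Default motif classes
#'
#' Three distinct motion classes ("reach", "stir", "lift"): each a sum of
#' 2--3 Gaussian-windowed sinusoids with class-specific frequencies, phases
#' and axis mixes, giving band-limited bursts that resemble reach/grab
#' accelerometry and remain distinguishable under DTW.
#'
#' @param amplitude length-2 range of peak amplitudes in m/s^2 (default
#'   `c(2.5, 4)`).
#' @return A named list of motif specs (`label`, `duration_s` range,
#'   `amplitude` range, component `freq_hz`, `phase`, and 3-column
#'   `axis_mix`).
#' @export
default_motif_classes <- function(amplitude = c(2.5, 4)) {
  list(
    reach = list(label = "reach", duration_s = c(1.5, 2.5), amplitude = amplitude,
                 freq_hz = c(1.2, 2.8), phase = c(0, 1.1),
                 axis_mix = rbind(c(1.0, 0.4, 0.2), c(0.3, 1.0, 0.1))),
    stir = list(label = "stir", duration_s = c(1.8, 3.0), amplitude = amplitude,
                freq_hz = c(3.6, 5.2, 1.4), phase = c(0.5, 2.0, 0.2),
                axis_mix = rbind(c(0.2, 1.0, 0.6), c(1.0, 0.2, 0.8),
                                 c(0.1, 0.5, 1.0))),
    lift = list(label = "lift", duration_s = c(1.2, 2.2), amplitude = amplitude,
                freq_hz = c(0.9, 6.5), phase = c(1.6, 0.8),
                axis_mix = rbind(c(0.6, 0.1, 1.0), c(0.2, 0.9, 0.4)))
  )
}

# Evaluate one motif instance on a time grid (seconds, relative to motif
# start); returns an n x 3 matrix. warp scales time, amp scales amplitude.
motif_signal <- function(spec, t, dur, amp) {
  center <- dur / 2
  sigma <- dur / 5  # Gaussian envelope: burst dies out at the span edges
  env <- exp(-(t - center)^2 / (2 * sigma^2))
  out <- matrix(0, length(t), 3)
  for (kc in seq_along(spec$freq_hz)) {
    # frequencies scale inversely with the time warp so a slow execution is
    # a genuinely slower motion, not a different one
    osc <- sin(2 * pi * spec$freq_hz[kc] * t * (spec$duration_s[1] / dur) +
                 spec$phase[kc])
    out <- out + outer(env * osc, spec$axis_mix[kc, ])
  }
  out * amp / max(length(spec$freq_hz), 1)
}

#' Generate a synthetic labeled recording
#'
#' One 3-axis stream: a constant gravity vector plus white Gaussian noise
#' plus planted motif bursts. Activities are placed non-overlapping with at
#' least `min_gap_s` between them and `idle_pad_s` of idle signal at both
#' ends; each instance draws its class (cycled), time-warp factor and
#' amplitude from the configured ranges. Ground-truth labels are written
#' exactly at the planted spans. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param recording_id identifier for the recording.
#' @param device stream device name.
#' @return A [recording()] with one stream and one label per activity.
#' @export
generate_recording <- function(cfg, recording_id = "sim_rec",
                               device = "wrist_right") {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, generate_recording_impl(cfg, recording_id, device))
}

generate_recording_impl <- function(cfg, recording_id, device) {
  fs <- cfg$sample_rate_hz
  n <- round(cfg$duration_s * fs)
  ts <- as.integer(round((seq_len(n) - 1) * 1000 / fs))
  vals <- matrix(rep(cfg$gravity, each = n), n, 3)
  if (cfg$noise_sd > 0) vals <- vals + matrix(stats::rnorm(3 * n, 0, cfg$noise_sd), n, 3)

  labels <- empty_labels()
  if (cfg$n_activities > 0) {
    classes <- rep(seq_along(cfg$motif_classes), length.out = cfg$n_activities)
    durs <- numeric(cfg$n_activities)
    amps <- numeric(cfg$n_activities)
    for (i in seq_len(cfg$n_activities)) {
      spec <- cfg$motif_classes[[classes[i]]]
      warp <- stats::runif(1, cfg$warp_factor_range[1], cfg$warp_factor_range[2])
      durs[i] <- stats::runif(1, spec$duration_s[1], spec$duration_s[2]) * warp
      amps[i] <- stats::runif(1, spec$amplitude[1], spec$amplitude[2])
    }
    # place activities: distribute the slack uniformly between them
    usable <- cfg$duration_s - 2 * cfg$idle_pad_s
    slack <- usable - sum(durs) - (cfg$n_activities - 1) * cfg$min_gap_s
    if (slack < 0) stop("infeasible packing after duration draws")
    cuts <- sort(stats::runif(cfg$n_activities, 0, slack))
    starts_s <- cfg$idle_pad_s + cuts +
      cumsum(c(0, utils::head(durs, -1) + cfg$min_gap_s))
    start_ms <- integer(cfg$n_activities)
    end_ms <- integer(cfg$n_activities)
    labs <- character(cfg$n_activities)
    for (i in seq_len(cfg$n_activities)) {
      spec <- cfg$motif_classes[[classes[i]]]
      i0 <- floor(starts_s[i] * fs) + 1
      i1 <- min(n, i0 + round(durs[i] * fs) - 1)
      tt <- (seq(i0, i1) - i0) / fs
      vals[i0:i1, ] <- vals[i0:i1, ] + motif_signal(spec, tt, durs[i], amps[i])
      start_ms[i] <- ts[i0]
      end_ms[i] <- ts[i1] + round(1000 / fs)
      labs[i] <- spec$label
    }
    labels <- label_intervals(start_ms, end_ms, labs)
  }
  st <- sensor_stream(ts, vals, channels = c("x", "y", "z"),
                      recording_id = recording_id, device = device,
                      sample_rate_hz = fs)
  recording(st, labels, recording_id = recording_id,
            metadata = list(seed = cfg$seed, noise_sd = cfg$noise_sd))
}

#' Generate a cohort of recordings
#'
#' Per-recording seeds are derived deterministically from the master seed,
#' so the whole cohort reproduces from one integer. With
#' `bilateral = TRUE` a second ("wrist_left") stream is added in which the
#' same motifs get extra time-warp and amplitude jitter -- the non-dominant
#' hand moves less consistently.
#'
#' @param cfg a [sim_config()]; its `seed` is the master seed.
#' @param n_recordings number of recordings (>= 1).
#' @param bilateral add a jittered left-wrist stream.
#' @return A list of [recording()]s sharing the motif classes.
#' @export
generate_cohort <- function(cfg, n_recordings, bilateral = FALSE) {
  stopifnot(n_recordings >= 1)
  lapply(seq_len(n_recordings), function(i) {
    ci <- cfg
    ci$seed <- (cfg$seed * 1000L + i) %% .Machine$integer.max
    rec <- generate_recording(ci, recording_id = sprintf("sim_rec_%02d", i))
    if (bilateral) {
      cl <- ci
      cl$seed <- (ci$seed + 500L) %% .Machine$integer.max
      # non-dominant hand: wider warp range, damped amplitude
      cl$warp_factor_range <- c(cfg$warp_factor_range[1] * 0.85,
                                cfg$warp_factor_range[2] * 1.15)
      cl$motif_classes <- lapply(cfg$motif_classes, function(m) {
        m$amplitude <- m$amplitude * 0.8
        m
      })
      left <- generate_recording(cl, recording_id = rec$recording_id,
                                 device = "wrist_left")
      rec$streams <- c(rec$streams, left$streams)
    }
    rec
  })
}

#' Ratio of motion to idle signal magnitude
#'
#' Sanity metric for the generator's signal-to-noise knob: the mean
#' linear-acceleration (gravity-removed) magnitude inside the planted label
#' spans divided by the same mean outside them. Grows with motif amplitude
#' and shrinks with `noise_sd`.
#'
#' @param rec a labeled [recording()].
#' @param alpha gravity-filter smoothing factor.
#' @param device stream to measure.
#' @return A positive number (ratio).
#' @export
magnitude_ratio <- function(rec, alpha = 0.8, device = NULL) {
  stream <- if (is.null(device)) rec$streams[[1]] else rec$streams[[device]]
  lin <- decompose_acceleration(stream, alpha)$linear
  mag <- sqrt(rowSums(lin$values^2))
  inside <- rep(FALSE, length(mag))
  for (i in seq_len(nrow(rec$labels))) {
    inside <- inside | (stream$timestamps >= rec$labels$start_ms[i] &
                          stream$timestamps < rec$labels$end_ms[i])
  }
  if (!any(inside) || all(inside)) {
    stop("validation error: need samples both inside and outside label spans")
  }
  mean(mag[inside]) / mean(mag[!inside])
}
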