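---
title: "Template matching for activity labeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template matching for activity labeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actispot)
```

## The problem

Annotating wearable-sensor recordings is slow: a rater has to scrub through
minutes of video or signal to place a handful of activity intervals.
`actispot` implements semi-supervised labeling support for this setting.
Given a few annotated intervals of wrist-worn accelerometer data, it
extracts signal *templates*, matches them against the unlabeled remainder
of the corpus with dynamic time warping (DTW), and proposes at most *k*
candidate spans per recording for the rater to confirm or discard. The
working assumption is that it is cheaper to reject a wrong suggestion than
to find a missed activity, so the selection rules favor recall over
precision.

Three scenario shapes are supported:

* **picking** — each recording contains (at least) one instance of a single
  short activity (e.g. grabbing an item from a shelf). A fixed-length
  template slides over the stream and the minimum-distance window wins
  (`sliding_fixed_match()`), optionally stabilized across templates by the
  self-consistent subset rule (`best_subset()`).
* **adl** — multiple activities per recording, one or two wrists.
  Subsequence DTW locates every plausible match and a top-*k* rule prunes
  the pool (`recommend()`).
* **complex** — activities composed of several motions (meal preparation).
  Templates are summarized as windowed feature sequences and clustered by
  motion similarity (`cluster_templates()`), revealing which semantically
  different labels share the same arm movement.

## Signal model and preprocessing

A `sensor_stream` holds integer-millisecond timestamps and one acceleration
vector per sample (m/s², nominally 40 Hz for the wristband, 50 Hz for
glasses-mounted IMUs). Android-style sensor stacks push samples with
jitter, so nothing assumes exact uniformity; operations that need a fixed
grid (windowed features, the FFT) resample first with
`resample_uniform()` (linear interpolation). Label intervals are half-open
`[start, end)` everywhere so abutting intervals do not overlap.

Matching operates on one of three representations selected by
`preprocess_config()`:

* **raw** acceleration;
* **gravity**: a first-order exponential low-pass per channel,
  `g[t] = alpha * g[t-1] + (1 - alpha) * a[t]`, seeded with the first
  sample. `alpha = 0.8` by default — the conventional wearable gravity
  filter constant; larger alpha = smoother, slower estimate;
* **linear**: the residual `a - g`, i.e. the motion component.

Optionally the three axes collapse to the Euclidean magnitude
(`reduce_to_magnitude()`), discarding orientation — which in practice often
generalizes better across wearers, at the price of losing directional
information. Axis angles (`axis_angles()`, `acos` of the normalized
components) are provided as an alternative orientation representation.
Since no filter order or cutoff is canonical here, both `alpha` and the
representation are explicit configuration, and every template records a
fingerprint of the configuration it was built with; matching against a
differently preprocessed stream is a hard error rather than a silent
degradation.

## Dynamic time warping

`dtw_full()` implements the textbook recursion

```
d(i, j) = cost(i, j) + min(d(i, j-1), d(i-1, j), d(i-1, j-1))
```

with Euclidean local cost, steps {(1,0), (0,1), (1,1)}, no step weights and
no band. Backtracking ties break deterministically (diagonal, then
vertical, then horizontal) so results are reproducible. The implementation
is a small C++ kernel; an exhaustive enumeration over all monotone warping
paths serves as the test oracle on tiny instances, so the dynamic program
is checked against a genuinely independent computation.

`dtw_subsequence()` is the free-start variant for locating a short query
inside a long stream: the first template row of the accumulated-cost matrix
is initialized to the local cost at every series position, so
`last_row[j]` is the cost of the best match *ending* at `j`. Start
positions and warping-path lengths are propagated cell-by-cell alongside
the costs (with the same tie-break as backtracking), so every end position
yields its matched span in O(1). Candidates are the strict local minima of
`last_row` (plateaus resolve to their leftmost index).

**Distance normalization.** Raw DTW cost grows with sequence length, which
biases any comparison across templates of different lengths — short
templates systematically look closer. By default every reported distance is
divided by its warping-path length; the unnormalized distance is retained,
and `normalize = FALSE` reproduces the length bias where one wants to study
it (it is visible in clustering, where short templates merge early).

## Candidate selection

Matching every template against a recording yields hundreds of local
minima; two rules prune the pooled list to at most *k* suggestions:

* **delta rule** (`select_topk_delta()`): greedy temporal non-maximum
  suppression. Candidates are visited in order of ascending distance and
  accepted only if their start lies at least `delta_ms` (default 2000 ms)
  from every accepted start. Activities of interest are assumed not to
  recur within two seconds, so an accepted candidate suppresses its
  neighborhood. The accepted set for `k` is a prefix of the set for
  `k + 1`, which makes recall non-decreasing in `k`.
* **zeroline rule** (`select_topk_zeroline()`): a null-template filter. A
  "zeroline" — a span of no movement, available at the start of every
  recording by protocol — is matched as if it were an activity template,
  and an activity candidate survives only if its distance is strictly
  smaller than the zeroline's distance at the same end position. Away from
  real activity the idle template should match at least as well, so
  surviving candidates indicate genuine motion. The filtered list is then
  truncated to the k smallest. The rule can legitimately return the empty
  set (the idle template wins everywhere); this mirrors how the filter
  behaves when the matched representation retains too much posture
  information.

Pooling happens across templates *before* selection; per-template selection
followed by merging is possible but makes `k` harder to interpret. The
delta rule measures separation between candidate *starts*: under the
spacing assumption two distinct activities differ in start time by more
than delta, while end times inherit warping noise.

## Templates

`extract_templates()` slices the preprocessed stream at each label interval
(for the hand the label names; unknown hands fall back to a configured
default device). `leading_ms` truncates each slice to the initial portion
of the activity — matching only the initial arm movement lets one template
family cover semantically different activities that begin with the same
reach. Zeroline templates are drawn from an annotated idle span or detected
by `detect_zeroline()` (rolling 1 s standard deviation of the magnitude
below 0.05 m/s² for at least 2 s), and truncated to the median activity-
template duration so idle and activity distances are computed over
comparable spans. The 0.05 m/s² default presumes a genuinely still idle
baseline; on noisier hardware it must be raised, or an explicit span
provided.

## Clustering complex activities

For composite activities the raw signal is too variable to compare
directly, so each template is summarized as a sequence of windowed
features: per window and channel, the spectral energy of the mean-removed
window (sum of squared non-DC DFT magnitudes scaled to per-sample power —
the biased variance, `A^2/2` for a full-period sinusoid of amplitude `A`)
and the unscaled median absolute deviation. Mean removal means a change of
posture (constant gravity offset) does not register as motion.

Two numerical choices matter and are deliberate:

* **Window geometry.** Generic feature extraction defaults to 32-sample
  (800 ms) windows with 50% overlap. Clustering uses 400 ms windows with a
  100 ms hop instead: templates are only 1–3 s long, and at 800/400 a
  template reduces to 2–6 windows, too coarse to retain the temporal
  structure that separates motion classes. On the package's synthetic
  motif fixture the coarse setting recovers the planted classes only
  partially, while 400/100 recovers them exactly at high SNR.
* **Feature standardization.** Energy is quadratic in amplitude and MAD
  linear, so unstandardized distances are dominated by how *hard* a motion
  was performed rather than *what* it was. Each feature dimension is
  z-scored across all templates' windows before DTW (`standardize = TRUE`).

The pairwise (path-length-normalized) DTW distances feed
`stats::hclust`; average linkage is the default since nothing canonical
dictates one (it sits between single's chaining and complete's compactness)
and the choice is recorded in the dendrogram object. `cut_dendrogram()`
renumbers flat clusters by their smallest member so partitions are
comparable across runs, and `export_newick()` writes the merge tree with
branch lengths derived from merge heights for standard tree tooling.

## Evaluation

* Temporal overlap is the Jaccard index of two spans (symmetric, bounded,
  1 iff equal); intersection-over-truth is available where a one-sided
  notion is wanted.
* `candidate_label_distance()` is 0 when a candidate overlaps any label and
  otherwise the gap to the nearest label, in seconds; sweeps aggregate it
  as min / median / max.
* `recall_at_k()` counts a label as found when any candidate overlaps it.
* `roc_curve()` runs a standard threshold sweep over fixed 1 s windows; a
  window is positive if it overlaps a label and scores the negated best
  match distance observed in it. Because subsequence DTW anchors distances
  at match *ends*, each distance is first spread over its full warped span
  — otherwise the first half of every activity scores as badly as idle.
* `leave_one_out()` evaluates the realistic protocol: templates from all
  recordings except the held-out one.

## The synthetic generator

No public corpus ships with the package, so `generate_recording()` emulates
the structure the method assumes: a 3-axis stream at 40 Hz, 60–180 s long
(default 90 s), constant gravity plus white Gaussian noise (default sd
0.25 m/s², a realistic resting-wrist figure), idle padding (default 5 s) at
both ends, and 0–4 non-overlapping activity bursts separated by at least
3 s — so a 2 s exclusion radius can in principle isolate every one. Motifs
are sums of 2–3 Gaussian-windowed sinusoids with class-specific frequencies
and axis mixes ("reach", "stir", "lift"); each instance draws a time-warp
factor (0.8–1.25, with frequencies scaled inversely so a slow execution is
the same motion performed slowly) and an amplitude (2.5–4 m/s²). Labels
are written exactly at the planted spans, and everything reproduces
byte-identically from one integer seed (`generate_cohort()` derives
per-recording seeds; bilateral mode adds a left-wrist stream with extra
warp and damped amplitude, emulating a less consistent non-dominant hand).

What the generator deliberately does *not* model: baseline drift and
sensor-axis miscalibration, correlated (pink) noise, posture changes
between activities, motion outside labeled spans (fidgeting), and
biomechanical coupling across axes. Tests passing on this generator
therefore demonstrate the pipeline's correctness and its behavior under
speed/amplitude variability and additive noise — not performance on any
particular real corpus.

Problem sizes used in the shipped test-suite experiments were chosen to
exercise the method at realistic scale while keeping runs quick: cohorts of
5–10 recordings of 60–90 s, 2–8 templates per evaluation, 3 × 5 templates
for clustering, and the exhaustive DTW oracle on sequences of length ≤ 7
(500 random instances). Where a test prescribes a signal-to-noise
condition, the noise level is set to meet it and the achieved
motion-to-idle magnitude ratio is asserted alongside (`magnitude_ratio()`),
so the condition is checked rather than assumed.

## Degenerate inputs and tie-breaks

* Duplicate timestamps keep the first sample; unsorted input is sorted.
* All-zero acceleration samples get axis angles of 0 with a warning
  (the direction is undefined).
* DTW backtracking and forward start-propagation use one fixed tie-break
  (diagonal > vertical > horizontal).
* `last_row` plateaus yield their leftmost index; selection ties break by
  (distance, start).
* `best_subset()` ties resolve to the lexicographically smallest index set
  and the exhaustive search refuses instances beyond 10^6 subsets.
* Timestamps may go negative after `shift_stream()`; trimming is the
  caller's decision.

## Known limitations

* The sliding fixed-length matcher constrains every detection to the
  template's duration; boundary accuracy suffers accordingly (visible as
  nonzero duration deltas even when overlap is high).
* The zeroline rule depends on the matched representation: when posture
  dominates (raw or gravity data, all three axes), the idle template can
  beat every activity template and the rule returns nothing.
* Clustering quality is sensitive to the feature window geometry for short
  templates; the defaults suit 1–3 s templates at 40 Hz.
* Only constant-offset time alignment between devices is provided;
  event-based alignment (matching walking peaks or first-activity onsets)
  must be done upstream.
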