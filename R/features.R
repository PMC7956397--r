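#' Segment a recording into the fixed window grid
#'
#' Splits a recording into consecutive, non-overlapping, equal-length
#' windows anchored at the first sample. A trailing partial window is
#' discarded, so the window count is `floor(N / round(ws_seconds * fs))`.
#' Both the classifier and the windowized reference annotations use this
#' identical grid, which guarantees equal-length label series.
#'
#' @param recording an [accel_recording()].
#' @param ws_seconds window size in seconds; `ws_seconds * sample_rate_hz`
#'   must lie within 0.5 of an integer >= 1 (all grid values are exact at
#'   25 Hz).
#' @return Data frame with one row per window: `window` (1-based index),
#'   `start_sample`, `end_sample` (inclusive), `start_s`, `end_s`
#'   (half-open interval in seconds).
#' @examples
#' rec <- accel_recording(matrix(0, 2500, 3,
#'                               dimnames = list(NULL, c("ax", "ay", "az"))))
#' nrow(segment_windows(rec, 4))  # 25 windows of 100 samples
#' @export
segment_windows <- function(recording, ws_seconds) {
  stopifnot(inherits(recording, "accel_recording"),
            is.numeric(ws_seconds), length(ws_seconds) == 1L,
            is.finite(ws_seconds), ws_seconds > 0)
  fs <- recording$sample_rate_hz
  n_per <- round(ws_seconds * fs)
  if (n_per < 1 || abs(ws_seconds * fs - n_per) > 0.5) {
    stop(sprintf(
      "window size %g s does not map onto the %g Hz sample grid", ws_seconds, fs))
  }
  n <- n_samples(recording)
  n_win <- floor(n / n_per)
  if (n_win < 1L) {
    stop(sprintf(
      "recording too short: %d samples, but one %g s window needs %d samples",
      n, ws_seconds, n_per))
  }
  idx <- seq_len(n_win)
  data.frame(window = idx,
             start_sample = (idx - 1L) * n_per + 1L,
             end_sample = idx * n_per,
             start_s = (idx - 1L) * n_per / fs,
             end_s = idx * n_per / fs)
}

#' Zero-phase band-pass of the dynamic (movement) component
#'
#' Isolates the movement component of each axis: the axis is demeaned, then
#' filtered with a Butterworth band-pass applied forward and backward
#' (zero-phase, no group delay). The default band of 0.25-11 Hz removes the
#' gravity component and slow orientation drift at the low end and sensor
#' noise above voluntary-movement frequencies at the high end, and sits
#' below the 12.5 Hz Nyquist frequency of the nominal 25 Hz signal. The
#' filter is applied to the whole recording once, before windowing, so
#' windows shorter than the filter transient remain well-defined.
#'
#' @param recording an [accel_recording()].
#' @param band two-element numeric, band edges in Hz.
#' @param order overall band-pass filter order (even; default 4).
#' @return Numeric matrix, same shape and column names as the recording's
#'   samples, in g.
#' @export
band_pass_dynamic <- function(recording, band = c(0.25, 11), order = 4) {
  stopifnot(inherits(recording, "accel_recording"),
            is.numeric(band), length(band) == 2L, all(band > 0),
            band[1] < band[2],
            is.numeric(order), length(order) == 1L, order >= 2,
            order %% 2 == 0)
  fs <- recording$sample_rate_hz
  if (band[2] >= fs / 2) {
    stop(sprintf("upper band edge %g Hz must lie below the Nyquist frequency %g Hz",
                 band[2], fs / 2))
  }
  filt <- signal::butter(order / 2, band / (fs / 2), type = "pass")
  out <- recording$samples
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    x <- x - mean(x)
    # an exactly-zero axis stays exactly zero (no filter round-off)
    out[, j] <- if (all(x == 0)) x else signal::filtfilt(filt, x)
  }
  out
}

#' Per-window sensor-orientation feature
#'
#' The orientation feature of a window is the mean of the raw
#' longitudinal-axis acceleration over that window, in g. For a motionless
#' sensor this equals the cosine of the angle between the thigh and the
#' gravity vector: +1 g when standing upright, about 0 g with the thigh
#' horizontal (sitting or lying). It is compared against the orientation
#' threshold SO Th; 0.8 g corresponds to roughly 37 degrees of thigh
#' inclination, well inside the 60-degree sedentary/upright boundary.
#'
#' @param recording an [accel_recording()].
#' @param ws_seconds window size in seconds (see [segment_windows()]).
#' @return Numeric vector, one orientation value (g) per window.
#' @export
orientation_feature <- function(recording, ws_seconds) {
  grid <- segment_windows(recording, ws_seconds)
  v <- axis_signal(recording, "longitudinal")
  window_means(v, grid)
}

#' Per-window activity counts
#'
#' Quantifies the amount of physical activity in each window in counts per
#' second (cps). The movement component of the signal (see
#' [band_pass_dynamic()]) is rectified, summed over the window, and divided
#' by the window duration; one count is 1 g-sample of rectified filtered
#' acceleration per second. In `"triaxial"` mode (MOXAL) the three axes'
#' rectified contributions are summed before normalizing; `"single_axis"`
#' mode (HFITAL) uses only the anterior-posterior axis, which carries the
#' most pronounced gait signal in slow or walking-aid-assisted gait and
#' avoids masking by quieter axes.
#'
#' @param recording an [accel_recording()].
#' @param ws_seconds window size in seconds.
#' @param mode `"single_axis"` or `"triaxial"`.
#' @param band,order counts-filter settings, see [band_pass_dynamic()].
#' @return Numeric vector of non-negative counts (cps), one per window.
#' @export
activity_counts <- function(recording, ws_seconds,
                            mode = c("single_axis", "triaxial"),
                            band = c(0.25, 11), order = 4) {
  mode <- match.arg(mode)
  grid <- segment_windows(recording, ws_seconds)
  dyn <- band_pass_dynamic(recording, band = band, order = order)
  fs <- recording$sample_rate_hz
  rect <- if (mode == "single_axis") {
    abs(dyn[, recording$axis_roles[["anterior_posterior"]]])
  } else {
    abs(dyn[, 1]) + abs(dyn[, 2]) + abs(dyn[, 3])
  }
  dur <- (grid$end_sample - grid$start_sample + 1L) / fs
  window_sums(rect, grid) / dur
}

#' Compute both per-window features of a recording
#'
#' Convenience wrapper running [segment_windows()], [orientation_feature()]
#' and [activity_counts()] on one grid.
#'
#' @inheritParams activity_counts
#' @return Data frame with columns `window`, `start_s`, `end_s`,
#'   `orientation_g`, `counts_cps`.
#' @examples
#' rec <- accel_recording(cbind(ax = rep(1, 250), ay = 0, az = 0))
#' window_features(rec, 2, mode = "single_axis")
#' @export
window_features <- function(recording, ws_seconds,
                            mode = c("single_axis", "triaxial"),
                            band = c(0.25, 11), order = 4) {
  mode <- match.arg(mode)
  grid <- segment_windows(recording, ws_seconds)
  data.frame(window = grid$window,
             start_s = grid$start_s,
             end_s = grid$end_s,
             orientation_g = orientation_feature(recording, ws_seconds),
             counts_cps = activity_counts(recording, ws_seconds, mode = mode,
                                          band = band, order = order))
}

# Windowed sums/means via cumulative sums (O(N) for any number of windows).
window_sums <- function(v, grid) {
  cs <- c(0, cumsum(v))
  cs[grid$end_sample + 1L] - cs[grid$start_sample]
}

window_means <- function(v, grid) {
  window_sums(v, grid) / (grid$end_sample - grid$start_sample + 1L)
}
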