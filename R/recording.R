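#' Construct a raw acceleration recording
#'
#' Container for a tri-axial acceleration trace in units of g. The device
#' model is a thigh-worn logger sampling three orthogonal axes at a nominal
#' 25 Hz with a \eqn{\pm 8} g range; samples outside that range or non-finite
#' values are rejected. `axis_roles` maps the anatomical roles onto the
#' sensor columns, since device mounting varies: the longitudinal axis runs
#' along the thigh (oriented so quiet standing reads +1 g), the
#' anterior-posterior axis points through the knee, and the medio-lateral
#' axis completes the triad. Any sign flips needed to reach that convention
#' must be applied before construction.
#'
#' @param samples numeric matrix (or data frame) with columns `ax`, `ay`,
#'   `az`, one row per sample, units of g.
#' @param sample_rate_hz positive sampling rate, nominally 25.
#' @param axis_roles named character vector mapping the roles
#'   `longitudinal`, `anterior_posterior`, `medio_lateral` onto the column
#'   names `ax`, `ay`, `az` (a bijection).
#' @param subject_id identifier string carried through reports.
#' @return An object of class `accel_recording`.
#' @examples
#' rec <- accel_recording(cbind(ax = rep(1, 50), ay = 0, az = 0))
#' rec
#' @export
accel_recording <- function(samples,
                            sample_rate_hz = 25,
                            axis_roles = c(longitudinal = "ax",
                                           anterior_posterior = "ay",
                                           medio_lateral = "az"),
                            subject_id = "subject") {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || ncol(samples) != 3L) {
    stop("`samples` must be a numeric matrix with 3 columns (ax, ay, az)")
  }
  if (is.null(colnames(samples))) colnames(samples) <- c("ax", "ay", "az")
  if (!setequal(colnames(samples), c("ax", "ay", "az"))) {
    stop("`samples` columns must be named ax, ay, az")
  }
  samples <- samples[, c("ax", "ay", "az"), drop = FALSE]
  if (nrow(samples) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite acceleration value at sample %d, axis %s",
                 bad[["row"]], colnames(samples)[bad[["col"]]]))
  }
  if (any(abs(samples) > 8)) {
    bad <- which(abs(samples) > 8, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "acceleration exceeds the sensor range of 8 g at sample %d, axis %s",
      bad[["row"]], colnames(samples)[bad[["col"]]]))
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a single positive number")
  }
  roles <- c("longitudinal", "anterior_posterior", "medio_lateral")
  if (!setequal(names(axis_roles), roles) ||
      !setequal(unname(axis_roles), c("ax", "ay", "az"))) {
    stop("`axis_roles` must be a bijection from ",
         paste(roles, collapse = ", "), " onto ax, ay, az")
  }
  structure(
    list(samples = samples,
         sample_rate_hz = as.numeric(sample_rate_hz),
         axis_roles = axis_roles[roles],
         subject_id = as.character(subject_id)),
    class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<accel_recording> subject '%s': %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, n, x$sample_rate_hz, n / x$sample_rate_hz))
  cat("  axis roles:",
      paste(sprintf("%s=%s", names(x$axis_roles), x$axis_roles),
            collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples and duration of a recording
#'
#' @param recording an [accel_recording()].
#' @return `n_samples()` the sample count; `rec_duration()` seconds.
#' @export
n_samples <- function(recording) {
  stopifnot(inherits(recording, "accel_recording"))
  nrow(recording$samples)
}

#' @rdname n_samples
#' @export
rec_duration <- function(recording) {
  n_samples(recording) / recording$sample_rate_hz
}

#' Extract one axis of a recording by anatomical role
#'
#' @param recording an [accel_recording()].
#' @param role one of `"longitudinal"`, `"anterior_posterior"`,
#'   `"medio_lateral"`.
#' @return Numeric vector of accelerations in g.
#' @export
axis_signal <- function(recording, role) {
  stopifnot(inherits(recording, "accel_recording"))
  role <- match.arg(role,
                    c("longitudinal", "anterior_posterior", "medio_lateral"))
  recording$samples[, recording$axis_roles[[role]]]
}

#' Algorithm parameter set
#'
#' The classification algorithm has three adjustable parameters: the data
#' segmentation window size WS (seconds), the amount-of-physical-activity
#' threshold PA Th (counts per second) separating standing from dynamic
#' windows, and the sensor-orientation threshold SO Th (g) separating
#' sedentary from upright windows. The `variant` selects the decision-tree
#' order and counts mode: `"moxal"` applies the activity threshold first and
#' computes tri-axial counts; `"hfital"` applies the orientation threshold
#' first and computes counts from the anterior-posterior axis only.
#'
#' @param ws_seconds window size in seconds; `ws_seconds * sample_rate` must
#'   round to at least one sample.
#' @param pa_th_cps activity threshold in counts per second, positive.
#' @param so_th_g orientation threshold in g, in (0, 1].
#' @param variant `"hfital"` or `"moxal"`.
#' @return An object of class `algorithm_params`.
#' @seealso [moxal_params()], [hfital_params()] for the named presets.
#' @export
algorithm_params <- function(ws_seconds, pa_th_cps, so_th_g = 0.8,
                             variant = c("hfital", "moxal")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(ws_seconds), length(ws_seconds) == 1L,
            is.finite(ws_seconds), ws_seconds > 0,
            is.numeric(pa_th_cps), length(pa_th_cps) == 1L,
            is.finite(pa_th_cps), pa_th_cps > 0,
            is.numeric(so_th_g), length(so_th_g) == 1L, is.finite(so_th_g))
  if (so_th_g <= 0 || so_th_g > 1) {
    stop("`so_th_g` must lie in (0, 1]: it is a gravity projection in g")
  }
  structure(
    list(ws_seconds = as.numeric(ws_seconds),
         pa_th_cps = as.numeric(pa_th_cps),
         so_th_g = as.numeric(so_th_g),
         variant = variant),
    class = "algorithm_params")
}

#' Preset parameter sets
#'
#' `moxal_params()` returns the baseline setting (WS 2 s, PA Th 7 cps,
#' SO Th 0.8 g, activity-first tree, tri-axial counts), validated for
#' community-dwelling elderly wearers. `hfital_params()` returns the setting
#' optimized for hospitalized patients (WS 4 s, PA Th 4.3 cps, SO Th 0.8 g,
#' posture-first tree, single-axis counts).
#'
#' @return An [algorithm_params()] object.
#' @export
moxal_params <- function() algorithm_params(2, 7, 0.8, "moxal")

#' @rdname moxal_params
#' @export
hfital_params <- function() algorithm_params(4, 4.3, 0.8, "hfital")

#' @export
print.algorithm_params <- function(x, ...) {
  cat(sprintf(
    "<algorithm_params> %s: WS %g s, PA Th %g cps, SO Th %g g (%s tree, %s counts)\n",
    toupper(x$variant), x$ws_seconds, x$pa_th_cps, x$so_th_g,
    if (x$variant == "hfital") "posture-first" else "activity-first",
    counts_mode(x)))
  invisible(x)
}

#' Counts mode implied by an algorithm variant
#'
#' HFITAL computes activity counts from the single most sensitive axis (the
#' anterior-posterior one, which dominates in slow or aided gait); MOXAL
#' combines all three axes.
#'
#' @param params an [algorithm_params()] object.
#' @return `"single_axis"` or `"triaxial"`.
#' @export
counts_mode <- function(params) {
  stopifnot(inherits(params, "algorithm_params"))
  if (params$variant == "hfital") "single_axis" else "triaxial"
}
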