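#' Classify feature windows with the HFITAL (posture-first) tree
#'
#' The optimized decision tree discriminates sedentary from upright windows
#' first: a window whose orientation feature falls below the orientation
#' threshold SO Th is sedentary regardless of its activity counts. Upright
#' windows are then split by the activity threshold PA Th: counts at or
#' above the threshold give a dynamic window, below it a standing window.
#' Threshold ties go upward (`orientation_g >= so_th_g` is upright,
#' `counts_cps >= pa_th_cps` is dynamic).
#'
#' @param features data frame from [window_features()], computed with
#'   `single_axis` counts for HFITAL or `triaxial` counts for MOXAL.
#' @param params an [algorithm_params()] with the matching `variant`.
#' @return Data frame `window`, `start_s`, `end_s`, `label` with labels in
#'   [ACTIVITY_LEVELS]; attributes `ws_seconds` and `variant` record the
#'   grid and tree used.
#' @export
classify_hfital <- function(features, params = hfital_params()) {
  check_features(features)
  stopifnot(inherits(params, "algorithm_params"))
  if (params$variant != "hfital") stop("`params$variant` must be \"hfital\"")
  lab <- ifelse(features$orientation_g < params$so_th_g, "sedentary",
                ifelse(features$counts_cps >= params$pa_th_cps,
                       "dynamic", "standing"))
  label_frame(features, lab, params)
}

#' Classify feature windows with the MOXAL (activity-first) tree
#'
#' The baseline decision tree applies the activity threshold first: a window
#' with counts at or above PA Th is dynamic regardless of orientation.
#' Remaining windows are split by the orientation threshold SO Th into
#' standing (at or above) and sedentary (below). This ordering is what the
#' posture-first modification of [classify_hfital()] changes: a window with
#' low orientation but high counts (e.g., leg movement while seated) is
#' dynamic under MOXAL but sedentary under HFITAL.
#'
#' @inheritParams classify_hfital
#' @export
classify_moxal <- function(features, params = moxal_params()) {
  check_features(features)
  stopifnot(inherits(params, "algorithm_params"))
  if (params$variant != "moxal") stop("`params$variant` must be \"moxal\"")
  lab <- ifelse(features$counts_cps >= params$pa_th_cps, "dynamic",
                ifelse(features$orientation_g >= params$so_th_g,
                       "standing", "sedentary"))
  label_frame(features, lab, params)
}

#' Dispatch classification on the parameter variant
#'
#' @inheritParams classify_hfital
#' @return See [classify_hfital()].
#' @export
classify_windows <- function(features, params) {
  stopifnot(inherits(params, "algorithm_params"))
  switch(params$variant,
         hfital = classify_hfital(features, params),
         moxal = classify_moxal(features, params))
}

check_features <- function(features) {
  if (!is.data.frame(features) ||
      !all(c("orientation_g", "counts_cps") %in% names(features))) {
    stop("`features` must be a data frame with orientation_g and counts_cps")
  }
  if (nrow(features) == 0L) stop("empty feature sequence: nothing to classify")
  invisible(features)
}

label_frame <- function(features, lab, params) {
  out <- data.frame(window = features$window,
                    start_s = features$start_s,
                    end_s = features$end_s,
                    label = lab)
  attr(out, "ws_seconds") <- params$ws_seconds
  attr(out, "variant") <- params$variant
  out
}

#' Coerce labels to a validated character vector
#'
#' Accepts either a label data frame (as returned by the classifiers or
#' [windowize_reference()]) or a bare character/factor vector, and checks
#' the closed vocabulary.
#'
#' @param x labels in either representation.
#' @return Character vector with values in [ACTIVITY_LEVELS].
#' @export
as_labels <- function(x) {
  v <- if (is.data.frame(x)) {
    if (!"label" %in% names(x)) stop("label data frame must have a `label` column")
    x$label
  } else {
    x
  }
  v <- as.character(v)
  bad <- setdiff(unique(v), ACTIVITY_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown activity label(s): ", paste(bad, collapse = ", "))
  }
  v
}

#' Detect postural transitions in a label series
#'
#' A postural transition is a sedentary window immediately followed by a
#' standing or dynamic window. Each window boundary (positions 2..n of the
#' series) receives flag 1 if it is such a transition and 0 otherwise; the
#' transition count is the sum of the flags. A series with fewer than two
#' windows has no boundaries: the result is zero transitions with an empty
#' flag vector.
#'
#' @param labels label series (data frame or character vector).
#' @return Object of class `transition_series`: list with `flags` (integer
#'   0/1 per boundary), `count`, and `boundary_time_s` when the input
#'   carries window times.
#' @examples
#' detect_transitions(c("sedentary", "sedentary", "standing", "dynamic"))
#' @export
detect_transitions <- function(labels) {
  v <- as_labels(labels)
  n <- length(v)
  times <- if (is.data.frame(labels) && "start_s" %in% names(labels) && n >= 2L) {
    labels$start_s[-1L]
  } else {
    NULL
  }
  if (n < 2L) {
    flags <- integer(0)
  } else {
    flags <- as.integer(v[-n] == "sedentary" & v[-1L] != "sedentary")
  }
  structure(list(flags = flags,
                 count = sum(flags),
                 boundary_time_s = times),
            class = "transition_series")
}

#' @export
print.transition_series <- function(x, ...) {
  cat(sprintf("<transition_series> %d boundaries, %d sedentary-to-upright transitions\n",
              length(x$flags), x$count))
  invisible(x)
}

#' Run the full classification pipeline on one recording
#'
#' Segments the recording, computes the features in the counts mode implied
#' by the parameter variant, classifies every window, and detects postural
#' transitions. The composition is deterministic: identical inputs always
#' produce identical outputs.
#'
#' @param recording an [accel_recording()].
#' @param params an [algorithm_params()].
#' @param band,order counts-filter settings, see [band_pass_dynamic()].
#' @return List with `features`, `labels` (label data frame) and
#'   `transitions` ([detect_transitions()] result).
#' @examples
#' rec <- accel_recording(cbind(ax = rep(1, 25 * 60), ay = 0, az = 0))
#' res <- run_pipeline(rec, hfital_params())
#' table(res$labels$label)  # a still upright minute is all standing
#' @export
run_pipeline <- function(recording, params, band = c(0.25, 11), order = 4) {
  stopifnot(inherits(recording, "accel_recording"),
            inherits(params, "algorithm_params"))
  feats <- window_features(recording, params$ws_seconds,
                           mode = counts_mode(params),
                           band = band, order = order)
  labels <- classify_windows(feats, params)
  attr(labels, "subject_id") <- recording$subject_id
  list(features = feats,
       labels = labels,
       transitions = detect_transitions(labels))
}
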