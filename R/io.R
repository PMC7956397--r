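#' Read a raw acceleration CSV
#'
#' Expects the header `time_s,ax_g,ay_g,az_g` with one row per sample,
#' monotone time at a nominal 25 Hz and accelerations in g within the
#' sensor range of \eqn{\pm 8} g. The sample rate is inferred from the
#' timestamps; when `sample_rate_hz` is supplied the inferred rate must
#' agree within 1%. Rows with missing, non-finite or out-of-range values
#' are reported by row number.
#'
#' @param path CSV file path.
#' @param sample_rate_hz optional expected rate for cross-checking.
#' @param axis_roles,subject_id passed to [accel_recording()];
#'   `subject_id` defaults to the file name without extension.
#' @return An [accel_recording()].
#' @export
read_accel_csv <- function(path, sample_rate_hz = NULL,
                           axis_roles = c(longitudinal = "ax",
                                          anterior_posterior = "ay",
                                          medio_lateral = "az"),
                           subject_id = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(df))) {
    stop("acceleration CSV must have header: ", paste(need, collapse = ","))
  }
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("missing or non-finite value in column %s at data row %d",
                   col, bad[1L]))
    }
  }
  for (col in c("ax_g", "ay_g", "az_g")) {
    bad <- which(abs(df[[col]]) > 8)
    if (length(bad) > 0L) {
      stop(sprintf("value outside the 8 g sensor range in column %s at data row %d",
                   col, bad[1L]))
    }
  }
  n <- nrow(df)
  if (n >= 2L) {
    dt <- diff(df$time_s)
    bad <- which(dt <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("non-monotone time at data row %d", bad[1L] + 1L))
    }
    fs_inferred <- (n - 1) / (df$time_s[n] - df$time_s[1L])
  } else {
    fs_inferred <- if (is.null(sample_rate_hz)) 25 else sample_rate_hz
  }
  if (!is.null(sample_rate_hz)) {
    if (abs(fs_inferred - sample_rate_hz) / sample_rate_hz > 0.01) {
      stop(sprintf(
        "sample rate inferred from timestamps (%.3f Hz) disagrees with the configured %g Hz by more than 1%%",
        fs_inferred, sample_rate_hz))
    }
    fs <- sample_rate_hz
  } else {
    fs <- fs_inferred
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  accel_recording(cbind(ax = df$ax_g, ay = df$ay_g, az = df$az_g),
                  sample_rate_hz = fs, axis_roles = axis_roles,
                  subject_id = subject_id)
}

#' Write a recording to the acceleration CSV format
#'
#' @param recording an [accel_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(recording, path) {
  stopifnot(inherits(recording, "accel_recording"))
  n <- n_samples(recording)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$sample_rate_hz,
                   ax_g = recording$samples[, "ax"],
                   ay_g = recording$samples[, "ay"],
                   az_g = recording$samples[, "az"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write reference annotation CSVs
#'
#' The reference format is `label,onset_s,offset_s` (a flattened,
#' observer-agnostic event export): contiguous, non-overlapping events
#' covering the measurement period. Validation errors cite the offending
#' intervals.
#'
#' @param path CSV file path.
#' @return `read_reference_csv()` a [reference_events()] table.
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("label", "onset_s", "offset_s")
  if (!all(need %in% names(df))) {
    stop("reference CSV must have header: ", paste(need, collapse = ","))
  }
  reference_events(df$label, df$onset_s, df$offset_s)
}

#' @rdname read_reference_csv
#' @param events a [reference_events()] table.
#' @export
write_reference_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("label", "onset_s", "offset_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write window label CSVs
#'
#' Format `window_index,start_s,end_s,label` with labels spelled
#' `sedentary|standing|dynamic`.
#'
#' @param labels a label data frame (from the classifiers or
#'   [windowize_reference()]).
#' @param path CSV file path.
#' @export
write_labels_csv <- function(labels, path) {
  stopifnot(is.data.frame(labels))
  df <- data.frame(window_index = labels$window,
                   start_s = labels$start_s,
                   end_s = labels$end_s,
                   label = as_labels(labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("window_index", "start_s", "end_s", "label")
  if (!all(need %in% names(df))) {
    stop("label CSV must have header: ", paste(need, collapse = ","))
  }
  data.frame(window = df$window_index, start_s = df$start_s,
             end_s = df$end_s, label = as_labels(df$label))
}

#' Write detected postural transitions to CSV
#'
#' Format `boundary_index,time_s`: one row per boundary flagged as a
#' sedentary-to-upright transition.
#'
#' @param transitions a [detect_transitions()] result computed from a
#'   label data frame (so boundary times are known).
#' @param path CSV file path.
#' @export
write_transitions_csv <- function(transitions, path) {
  stopifnot(inherits(transitions, "transition_series"))
  hit <- which(transitions$flags == 1L)
  times <- if (is.null(transitions$boundary_time_s)) {
    rep(NA_real_, length(hit))
  } else {
    transitions$boundary_time_s[hit]
  }
  utils::write.csv(data.frame(boundary_index = hit, time_s = times),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a validation report as JSON
#'
#' Serializes a per-subject report and/or cohort summary together with a
#' reproducibility stamp: the exact parameter set, counts-filter settings,
#' package version and creation time (the timestamp is informational and
#' excluded from idempotency comparisons).
#'
#' @param path output JSON path.
#' @param params the [algorithm_params()] used.
#' @param reports optional list of [subject_report()] data frames.
#' @param summary optional [cohort_summary()] data frame.
#' @param band,order counts-filter settings recorded for provenance.
#' @param seed optional seed recorded for provenance.
#' @export
write_report_json <- function(path, params, reports = NULL, summary = NULL,
                              band = c(0.25, 11), order = 4, seed = NULL) {
  stopifnot(inherits(params, "algorithm_params"))
  payload <- list(
    provenance = list(
      package = "hfital",
      version = as.character(utils::packageVersion("hfital")),
      variant = params$variant,
      ws_seconds = params$ws_seconds,
      pa_th_cps = params$pa_th_cps,
      so_th_g = params$so_th_g,
      counts_filter = list(band_hz = band, order = order),
      seed = seed,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    subjects = if (is.null(reports)) NULL else
      lapply(reports, function(r) as.data.frame(r)),
    cohort = if (is.null(summary)) NULL else as.data.frame(summary))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value configuration covering the algorithm parameters and the
#' signal contract. Recognized keys (with defaults):
#' `sample_rate_hz` (25), `variant` ("hfital"), `ws_seconds`,
#' `pa_th_cps`, `so_th_g` (variant preset values), `filter_band_hz`
#' (`[0.25, 11]`), `filter_order` (4), `axis_roles` (mapping of
#' longitudinal / anterior_posterior / medio_lateral to ax/ay/az),
#' `axis_signs` (per-axis +1/-1 flips applied at load), `offset_s`
#' (manual alignment shift, default 0), `aggregate` ("median"). A
#' commented template ships at
#' `system.file("extdata", "config-template.yaml", package = "hfital")`.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return A validated named list with all fields populated; element
#'   `params` holds the assembled [algorithm_params()].
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  variant <- tolower(cfg$variant %||% "hfital")
  preset <- if (variant == "moxal") moxal_params() else hfital_params()
  roles_in <- cfg$axis_roles %||% list(longitudinal = "ax",
                                       anterior_posterior = "ay",
                                       medio_lateral = "az")
  roles <- unlist(roles_in)
  params <- algorithm_params(
    ws_seconds = cfg$ws_seconds %||% preset$ws_seconds,
    pa_th_cps = cfg$pa_th_cps %||% preset$pa_th_cps,
    so_th_g = cfg$so_th_g %||% preset$so_th_g,
    variant = variant)
  signs <- unlist(cfg$axis_signs %||% list(ax = 1, ay = 1, az = 1))
  if (!setequal(names(signs), c("ax", "ay", "az")) || !all(signs %in% c(-1, 1))) {
    stop("`axis_signs` must map ax, ay, az to +1 or -1")
  }
  list(sample_rate_hz = cfg$sample_rate_hz %||% 25,
       params = params,
       filter_band_hz = as.numeric(cfg$filter_band_hz %||% c(0.25, 11)),
       filter_order = cfg$filter_order %||% 4,
       axis_roles = roles,
       axis_signs = signs[c("ax", "ay", "az")],
       offset_s = cfg$offset_s %||% 0,
       aggregate = cfg$aggregate %||% "median")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
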