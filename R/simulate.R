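#' Build an activity script for the synthetic-recording generator
#'
#' A script is an ordered sequence of activity bouts with the physical
#' parameters of the kinematic model. The thigh is reduced to a single
#' inclination angle: 90 degrees from gravity (horizontal) while sedentary,
#' 0 degrees (upright) while standing or dynamic, interpolated linearly
#' over `transition_ramp_s` seconds centred on each posture change.
#' Dynamic bouts add a sinusoidal gait oscillation on the
#' anterior-posterior axis (amplitude `ap_amplitude_g` at
#' `step_frequency_hz`) and optionally on the longitudinal axis
#' (`vertical_amplitude_g`, 90 degrees out of phase). Standing bouts may
#' carry a small `sway_amplitude_g` oscillation on the anterior-posterior
#' axis (`sway_frequency_hz`), emulating weight shifts and fidgeting; it
#' defaults to zero. White Gaussian sensor noise with `noise_sd_g` is added
#' to all axes.
#'
#' @param segments data frame with columns `label` (see [ACTIVITY_LEVELS])
#'   and `duration_s`, plus optional per-bout columns `step_frequency_hz`
#'   (default 1.8), `ap_amplitude_g` (default 0), `vertical_amplitude_g`
#'   (default 0), `sway_amplitude_g` (default 0), `sway_frequency_hz`
#'   (default 0.8).
#' @param transition_ramp_s posture-change ramp duration (s), default 2.
#' @param noise_sd_g standard deviation of the sensor noise in g.
#' @param seed integer seed making the generated noise reproducible;
#'   `NULL` draws from the current RNG state.
#' @return Object of class `activity_script`.
#' @export
activity_script <- function(segments, transition_ramp_s = 2,
                            noise_sd_g = 0.02, seed = NULL) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L,
            all(c("label", "duration_s") %in% names(segments)))
  segments$label <- as_labels(segments$label)
  defaults <- c(step_frequency_hz = 1.8, ap_amplitude_g = 0,
                vertical_amplitude_g = 0, sway_amplitude_g = 0,
                sway_frequency_hz = 0.8)
  for (col in names(defaults)) {
    if (!col %in% names(segments)) segments[[col]] <- defaults[[col]]
    segments[[col]][is.na(segments[[col]])] <- defaults[[col]]
  }
  if (any(segments$duration_s <= 0)) stop("bout durations must be positive")
  if (any(segments$ap_amplitude_g < 0) ||
      any(segments$vertical_amplitude_g < 0) ||
      any(segments$sway_amplitude_g < 0)) {
    stop("oscillation amplitudes must be non-negative")
  }
  stopifnot(is.numeric(transition_ramp_s), transition_ramp_s >= 0,
            is.numeric(noise_sd_g), noise_sd_g >= 0)
  if (any(segments$step_frequency_hz <= 0 | segments$step_frequency_hz >= 12.5)) {
    stop("`step_frequency_hz` must lie in (0, 12.5) Hz (below Nyquist at 25 Hz)")
  }
  if (any(segments$duration_s < transition_ramp_s)) {
    stop("every bout must last at least `transition_ramp_s` seconds")
  }
  structure(list(segments = segments,
                 transition_ramp_s = transition_ramp_s,
                 noise_sd_g = noise_sd_g,
                 seed = seed),
            class = "activity_script")
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize one subject's recording and ground truth from a script
#'
#' Renders the script's kinematic model into a tri-axial recording:
#' longitudinal axis `cos(theta) + vertical gait + noise`,
#' anterior-posterior axis `sin(theta) + gait/sway oscillation + noise`,
#' medio-lateral axis pure noise, with `theta` the thigh-to-gravity angle
#' trajectory described in [activity_script()]. The ground-truth reference
#' events reproduce the script's bout boundaries exactly (adjacent bouts of
#' the same label are merged). Fully reproducible from the script's seed.
#'
#' @param script an [activity_script()].
#' @param sample_rate_hz sampling rate, nominally 25 Hz.
#' @param subject_id identifier for the generated recording.
#' @return Object of class `simulated_subject`: list with `recording`
#'   (an [accel_recording()]), `truth` (a [reference_events()] table) and
#'   `script`.
#' @examples
#' sc <- activity_script(data.frame(label = "standing", duration_s = 60),
#'                       noise_sd_g = 0, seed = 1)
#' sub <- simulate_subject(sc)
#' range(axis_signal(sub$recording, "longitudinal"))  # constant 1 g
#' @export
simulate_subject <- function(script, sample_rate_hz = 25,
                             subject_id = "sim01") {
  stopifnot(inherits(script, "activity_script"))
  seg <- script$segments
  fs <- sample_rate_hz
  onsets <- cumsum(c(0, seg$duration_s))
  total <- onsets[length(onsets)]
  # truncate so the recording never outlasts the annotated period
  n <- floor(total * fs)
  t <- (seq_len(n) - 1) / fs
  si <- findInterval(t, onsets, rightmost.closed = FALSE)
  si[si > nrow(seg)] <- nrow(seg)

  theta_seg <- ifelse(seg$label == "sedentary", 90, 0)
  theta <- theta_seg[si]
  r <- script$transition_ramp_s
  if (r > 0 && nrow(seg) > 1L) {
    for (b in 2:nrow(seg)) {
      from <- theta_seg[b - 1L]
      to <- theta_seg[b]
      if (from == to) next
      tb <- onsets[b]
      mask <- t >= tb - r / 2 & t < tb + r / 2
      theta[mask] <- from + (to - from) * (t[mask] - (tb - r / 2)) / r
    }
  }
  th <- theta * pi / 180

  phase <- t - onsets[si]
  ap_osc <- numeric(n)
  vert_osc <- numeric(n)
  dyn <- seg$label[si] == "dynamic"
  if (any(dyn)) {
    w <- 2 * pi * seg$step_frequency_hz[si[dyn]]
    ap_osc[dyn] <- seg$ap_amplitude_g[si[dyn]] * sin(w * phase[dyn])
    vert_osc[dyn] <- seg$vertical_amplitude_g[si[dyn]] * cos(w * phase[dyn])
  }
  stand <- seg$label[si] == "standing"
  if (any(stand)) {
    w <- 2 * pi * seg$sway_frequency_hz[si[stand]]
    ap_osc[stand] <- seg$sway_amplitude_g[si[stand]] * sin(w * phase[stand])
  }

  noise <- with_seed(script$seed,
                     matrix(stats::rnorm(3L * n, 0, script$noise_sd_g),
                            ncol = 3L))
  samples <- cbind(ax = cos(th) + vert_osc + noise[, 1L],
                   ay = sin(th) + ap_osc + noise[, 2L],
                   az = noise[, 3L])

  keep <- c(TRUE, seg$label[-1L] != seg$label[-nrow(seg)])
  starts <- onsets[-length(onsets)][keep]
  truth <- reference_events(label = seg$label[keep],
                            onset_s = starts,
                            offset_s = c(starts[-1L], total))

  structure(list(recording = accel_recording(samples, sample_rate_hz = fs,
                                             subject_id = subject_id),
                 truth = truth,
                 script = script),
            class = "simulated_subject")
}

#' @export
print.simulated_subject <- function(x, ...) {
  cat(sprintf("<simulated_subject> '%s': %d bouts, %.1f min, %d transitions in truth\n",
              x$recording$subject_id, nrow(x$script$segments),
              rec_duration(x$recording) / 60,
              sum(x$truth$label[-nrow(x$truth)] == "sedentary" &
                    x$truth$label[-1L] != "sedentary")))
  invisible(x)
}

# Scenario parameter regimes. Amplitudes are in g, durations in seconds.
# "orthopedic" emulates post-surgery patients walking slowly with an aid;
# "elderly_shuffling" draws smaller gait amplitudes and slower cadence,
# emulating shuffling gait that sits closer to standing; "well_separated"
# is a calibration regime with bout durations on a 4 s lattice, a wide
# standing/dynamic counts gap and near-zero noise, so that a correctly
# implemented pipeline classifies it perfectly.
scenario_defaults <- function(scenario) {
  switch(scenario,
    orthopedic = list(
      gait_amplitude_range = c(0.35, 0.60),
      vertical_fraction_range = c(0.4, 0.8),
      sway_amplitude_range = c(0.02, 0.10),
      step_frequency_range = c(1.5, 2.0),
      noise_sd_g = 0.02,
      n_cycles_range = c(2L, 4L),
      sed_range = c(40, 120), dyn_range = c(40, 100), stand_range = c(16, 50),
      grid_aligned = FALSE),
    elderly_shuffling = list(
      gait_amplitude_range = c(0.12, 0.35),
      vertical_fraction_range = c(0.2, 0.5),
      sway_amplitude_range = c(0.03, 0.15),
      step_frequency_range = c(1.0, 1.6),
      noise_sd_g = 0.02,
      n_cycles_range = c(2L, 4L),
      sed_range = c(60, 150), dyn_range = c(30, 90), stand_range = c(16, 50),
      grid_aligned = FALSE),
    well_separated = list(
      gait_amplitude_range = c(0.50, 0.60),
      vertical_fraction_range = c(0.4, 0.6),
      sway_amplitude_range = c(0.04, 0.08),
      step_frequency_range = c(1.8, 2.0),
      noise_sd_g = 0.005,
      n_cycles_range = c(2L, 3L),
      sed_range = c(40, 100), dyn_range = c(40, 100), stand_range = c(16, 48),
      grid_aligned = TRUE),
    stop("unknown scenario: ", scenario))
}

#' Draw one scenario script
#'
#' Draws a hospital-session activity script from a scenario's documented
#' parameter distributions. Sessions follow a cycle template
#' sedentary / dynamic / standing / dynamic (rising from sitting directly
#' into walking, as sit-to-walk is the common hospital pattern), repeated
#' 2-4 times and closed with a final sedentary bout, which guarantees at
#' least one bout of every activity and at least one postural transition
#' per session. Bout durations, gait amplitude, cadence and standing sway
#' are drawn uniformly from the scenario's ranges; in the
#' `well_separated` calibration scenario durations are rounded onto a 4 s
#' lattice so that bout boundaries align with the window grid.
#'
#' @param scenario `"orthopedic"`, `"elderly_shuffling"` or
#'   `"well_separated"`.
#' @param seed integer seed for the draw (also seeds the script's noise).
#' @param gait_amplitude_range,sway_amplitude_range optional two-element
#'   overrides of the scenario's amplitude ranges (g).
#' @param n_cycles optional fixed number of template cycles.
#' @return An [activity_script()].
#' @export
scenario_script <- function(scenario = c("orthopedic", "elderly_shuffling",
                                         "well_separated"),
                            seed = NULL,
                            gait_amplitude_range = NULL,
                            sway_amplitude_range = NULL,
                            n_cycles = NULL) {
  scenario <- match.arg(scenario)
  p <- scenario_defaults(scenario)
  if (!is.null(gait_amplitude_range)) p$gait_amplitude_range <- gait_amplitude_range
  if (!is.null(sway_amplitude_range)) p$sway_amplitude_range <- sway_amplitude_range
  with_seed(seed, {
    k <- if (!is.null(n_cycles)) n_cycles else
      sample(seq(p$n_cycles_range[1L], p$n_cycles_range[2L]), 1L)
    dur <- function(rng) {
      d <- stats::runif(1L, rng[1L], rng[2L])
      if (p$grid_aligned) max(4, round(d / 4) * 4) else d
    }
    rows <- list()
    for (i in seq_len(k)) {
      step_f <- stats::runif(1L, p$step_frequency_range[1L], p$step_frequency_range[2L])
      amp1 <- stats::runif(1L, p$gait_amplitude_range[1L], p$gait_amplitude_range[2L])
      amp2 <- stats::runif(1L, p$gait_amplitude_range[1L], p$gait_amplitude_range[2L])
      vf <- stats::runif(1L, p$vertical_fraction_range[1L], p$vertical_fraction_range[2L])
      sway <- stats::runif(1L, p$sway_amplitude_range[1L], p$sway_amplitude_range[2L])
      rows[[length(rows) + 1L]] <- data.frame(
        label = c("sedentary", "dynamic", "standing", "dynamic"),
        duration_s = c(dur(p$sed_range), dur(p$dyn_range),
                       dur(p$stand_range), dur(p$dyn_range)),
        step_frequency_hz = step_f,
        ap_amplitude_g = c(0, amp1, 0, amp2),
        vertical_amplitude_g = c(0, amp1 * vf, 0, amp2 * vf),
        sway_amplitude_g = c(0, 0, sway, 0))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      label = "sedentary", duration_s = dur(p$sed_range),
      step_frequency_hz = 1.8, ap_amplitude_g = 0,
      vertical_amplitude_g = 0, sway_amplitude_g = 0)
    segments <- do.call(rbind, rows)
    noise_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    activity_script(segments, transition_ramp_s = 2,
                    noise_sd_g = p$noise_sd_g, seed = noise_seed)
  })
}

#' Simulate a cohort of subjects
#'
#' Draws `n_subjects` independent scenario scripts (see
#' [scenario_script()]) and renders each into a recording plus ground-truth
#' annotations. All randomness flows from the single master seed: each
#' subject receives a derived child seed, so cohorts are reproducible and
#' individual subjects are independent of cohort size ordering.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param scenario scenario name, see [scenario_script()].
#' @param seed master integer seed.
#' @param gait_amplitude_range,sway_amplitude_range,n_cycles optional
#'   overrides passed to [scenario_script()] (the override replaces the
#'   range but consumes the same random draws, so two cohorts generated
#'   from one seed that differ only in a range are identical in every
#'   other respect).
#' @param sample_rate_hz sampling rate of the generated recordings.
#' @return List of [simulate_subject()] results, ids `sim01`, `sim02`, ...
#' @examples
#' cohort <- simulate_cohort(2, "orthopedic", seed = 7)
#' cohort[[1]]
#' @export
simulate_cohort <- function(n_subjects,
                            scenario = c("orthopedic", "elderly_shuffling",
                                         "well_separated"),
                            seed = 1,
                            gait_amplitude_range = NULL,
                            sway_amplitude_range = NULL,
                            n_cycles = NULL,
                            sample_rate_hz = 25) {
  scenario <- match.arg(scenario)
  stopifnot(is.numeric(n_subjects), length(n_subjects) == 1L, n_subjects >= 1)
  child <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_subjects))
  lapply(seq_len(n_subjects), function(i) {
    sc <- scenario_script(scenario, seed = child[i],
                          gait_amplitude_range = gait_amplitude_range,
                          sway_amplitude_range = sway_amplitude_range,
                          n_cycles = n_cycles)
    simulate_subject(sc, sample_rate_hz = sample_rate_hz,
                     subject_id = sprintf("sim%02d", i))
  })
}
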