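#' Enumerate the parameter-optimization grid
#'
#' The search lattice over the two adjusted parameters: window size WS from
#' 0.4 s to 10 s in steps of 0.4 s (25 values) crossed with activity
#' threshold PA Th from 2 cps to 6 cps in steps of 0.025 cps (161 values),
#' 4025 combinations in total, in row-major order (WS outer, PA Th inner).
#' The orientation threshold is held fixed at 0.8 g throughout the search.
#' Lattice values are generated as integer index times step so that the
#' endpoints are exact.
#'
#' @param so_th_g fixed orientation threshold, default 0.8 g.
#' @return Data frame `ws_seconds`, `pa_th_cps`, `so_th_g` with 4025 rows;
#'   attributes `ws_values` and `pa_th_values` hold the two axes.
#' @examples
#' nrow(enumerate_grid())  # 4025
#' @export
enumerate_grid <- function(so_th_g = 0.8) {
  ws <- (4 * (1:25)) / 10          # 0.4 .. 10.0 s
  pa <- (2000 + 25 * (0:160)) / 1000  # 2.000 .. 6.000 cps
  grid <- data.frame(ws_seconds = rep(ws, each = length(pa)),
                     pa_th_cps = rep(pa, times = length(ws)),
                     so_th_g = so_th_g)
  attr(grid, "ws_values") <- ws
  attr(grid, "pa_th_values") <- pa
  grid
}

# Accept either a simulated_subject or a list(recording=, events=/truth=).
subject_recording <- function(s) {
  if (inherits(s, "simulated_subject")) return(s$recording)
  if (!is.null(s$recording)) return(s$recording)
  stop("cohort subject has no `recording`")
}

subject_events <- function(s) {
  if (inherits(s, "simulated_subject")) return(s$truth)
  ev <- if (!is.null(s$events)) s$events else s$truth
  if (is.null(ev)) stop("cohort subject has no reference `events`")
  ev
}

#' Grid-search the window size and activity threshold over a cohort
#'
#' Reproduces the optimization procedure: for every grid point, every
#' subject's recording is run through the full pipeline (segmentation,
#' features in the variant's counts mode, decision tree), the
#' total-activity absolute percentage error (APE) against the subject's
#' reference annotations is computed, and the per-subject errors are
#' aggregated across the cohort (median by default, mean available). The
#' parameter pair minimizing the aggregated total APE is returned; ties
#' resolve to the first grid point in row-major (WS, then PA Th) order, so
#' the result is deterministic. A subject too short to hold one window at
#' some WS is excluded at that grid point with a warning.
#'
#' The expensive signal-processing stages do not depend on the searched
#' parameters, so they are hoisted: the counts filter runs once per
#' recording, window features once per (subject, WS), and only the
#' threshold comparison is evaluated per PA Th value. The resulting
#' objective values are identical to running [run_pipeline()] and
#' [subject_report()] at each grid point.
#'
#' @param cohort list of subjects, each a [simulate_subject()] result or a
#'   `list(recording =, events =)` pair.
#' @param variant `"hfital"` or `"moxal"` (tree order and counts mode).
#' @param grid parameter grid from [enumerate_grid()].
#' @param aggregate cohort aggregation of per-subject total APE.
#' @param band,order counts-filter settings, see [band_pass_dynamic()].
#' @return List of class `grid_result`: `surface` (the grid with an
#'   `objective_ape_pct` column and `n_subjects` used per point), `best`
#'   ([algorithm_params()] attaining the minimum), `objective_ape_pct` (the
#'   minimal value).
#' @export
optimize_params <- function(cohort, variant = c("hfital", "moxal"),
                            grid = enumerate_grid(),
                            aggregate = c("median", "mean"),
                            band = c(0.25, 11), order = 4) {
  variant <- match.arg(variant)
  aggregate <- match.arg(aggregate)
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  agg_fun <- if (aggregate == "median") stats::median else mean
  mode <- if (variant == "hfital") "single_axis" else "triaxial"

  ws_values <- unique(grid$ws_seconds)
  pa_values <- unique(grid$pa_th_cps)
  so_th <- grid$so_th_g[1L]

  # Per subject: rectified filtered movement signal and raw longitudinal
  # axis, as cumulative sums so any window grid is O(1) per window.
  prep <- lapply(cohort, function(s) {
    rec <- subject_recording(s)
    dyn <- band_pass_dynamic(rec, band = band, order = order)
    rect <- if (mode == "single_axis") {
      abs(dyn[, rec$axis_roles[["anterior_posterior"]]])
    } else {
      abs(dyn[, 1]) + abs(dyn[, 2]) + abs(dyn[, 3])
    }
    list(fs = rec$sample_rate_hz,
         n = nrow(rec$samples),
         cs_rect = c(0, cumsum(rect)),
         cs_long = c(0, cumsum(rec$samples[, rec$axis_roles[["longitudinal"]]])),
         events = subject_events(s))
  })

  # objective[pa, ws] matrix, filled column by column
  obj <- matrix(NA_real_, nrow = length(pa_values), ncol = length(ws_values))
  nsub <- matrix(0L, nrow = length(pa_values), ncol = length(ws_values))

  for (wi in seq_along(ws_values)) {
    ws <- ws_values[wi]
    ape <- matrix(NA_real_, nrow = length(pa_values), ncol = length(prep))
    used <- 0L
    for (si in seq_along(prep)) {
      p <- prep[[si]]
      n_per <- round(ws * p$fs)
      n_win <- floor(p$n / n_per)
      if (n_win < 1L) {
        warning(sprintf(
          "subject %d too short for WS %g s: excluded at this grid point",
          si, ws))
        next
      }
      used <- used + 1L
      starts <- (seq_len(n_win) - 1L) * n_per
      counts <- (p$cs_rect[starts + n_per + 1L] - p$cs_rect[starts + 1L]) /
        (n_per / p$fs)
      orient <- (p$cs_long[starts + n_per + 1L] - p$cs_long[starts + 1L]) / n_per
      refw <- windowize_reference(p$events, ws, n_win)$label
      ref_t <- vapply(ACTIVITY_LEVELS, function(cl) sum(refw == cl), 0) * ws
      tot_t <- n_win * ws
      upright <- orient >= so_th
      if (variant == "hfital") {
        n_sed <- sum(!upright)
        cnt_up <- counts[upright]
        for (pi in seq_along(pa_values)) {
          n_dyn <- sum(cnt_up >= pa_values[pi])
          algo_t <- c(n_sed, length(cnt_up) - n_dyn, n_dyn) * ws
          ape[pi, si] <- sum(abs(ref_t - algo_t)) / tot_t * 100
        }
      } else {
        for (pi in seq_along(pa_values)) {
          is_dyn <- counts >= pa_values[pi]
          n_dyn <- sum(is_dyn)
          n_stand <- sum(!is_dyn & upright)
          algo_t <- c(n_win - n_dyn - n_stand, n_stand, n_dyn) * ws
          ape[pi, si] <- sum(abs(ref_t - algo_t)) / tot_t * 100
        }
      }
    }
    if (used > 0L) {
      obj[, wi] <- apply(ape, 1L, function(v) agg_fun(v[!is.na(v)]))
      nsub[, wi] <- used
    }
  }

  surface <- data.frame(ws_seconds = rep(ws_values, each = length(pa_values)),
                        pa_th_cps = rep(pa_values, times = length(ws_values)),
                        so_th_g = so_th,
                        objective_ape_pct = as.vector(obj),
                        n_subjects = as.vector(nsub))
  defined <- which(!is.na(surface$objective_ape_pct))
  if (length(defined) == 0L) stop("no grid point could be evaluated")
  best_i <- defined[which.min(surface$objective_ape_pct[defined])]
  best <- algorithm_params(surface$ws_seconds[best_i],
                           surface$pa_th_cps[best_i],
                           so_th, variant)
  structure(list(surface = surface,
                 best = best,
                 objective_ape_pct = surface$objective_ape_pct[best_i],
                 aggregate = aggregate),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(
    "<grid_result> %d grid points; best %s total APE %.3f%% at WS %g s, PA Th %g cps\n",
    nrow(x$surface), x$aggregate, x$objective_ape_pct,
    x$best$ws_seconds, x$best$pa_th_cps))
  invisible(x)
}
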