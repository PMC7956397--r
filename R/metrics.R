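#' One-vs-rest confusion counts for a target class
#'
#' Binarizes both label series against one target class and counts windows:
#' TP = windows classified as the target by both algorithm and reference,
#' FP = algorithm says target but reference does not, TN = neither does,
#' FN = reference says target but the algorithm does not. For
#' `target = "transition"` both series are first converted to boundary flag
#' arrays by [detect_transitions()] and the flags are compared
#' position-wise, so the counts refer to window boundaries rather than
#' windows.
#'
#' @param algo,ref label series (data frames or character vectors) of equal
#'   length on the same window grid.
#' @param target one of [ACTIVITY_LEVELS] or `"transition"`.
#' @return Object of class `confusion_counts`: list with `target`, `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(algo, ref, target) {
  target <- match.arg(target, c(ACTIVITY_LEVELS, "transition"))
  a <- as_labels(algo)
  r <- as_labels(ref)
  if (length(a) != length(r)) {
    stop(sprintf(
      "label series lengths differ (%d vs %d): algorithm and reference must share one window grid",
      length(a), length(r)))
  }
  if (target == "transition") {
    pa <- detect_transitions(algo)$flags == 1L
    pr <- detect_transitions(ref)$flags == 1L
  } else {
    pa <- a == target
    pr <- r == target
  }
  structure(list(target = target,
                 tp = sum(pa & pr), fp = sum(pa & !pr),
                 tn = sum(!pa & !pr), fn = sum(!pa & pr)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> target %s: TP %d, FP %d, TN %d, FN %d\n",
              x$target, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Standard one-vs-rest definitions, expressed as percentages:
#' sensitivity = TP / (TP + FN) x 100, specificity = TN / (TN + FP) x 100,
#' accuracy = (TP + TN) / (TP + FP + TN + FN) x 100. A ratio with a zero
#' denominator (e.g., no reference windows of the target class) is
#' undefined and returned as `NA`; such values are excluded from cohort
#' aggregation rather than imputed.
#'
#' @param counts a [confusion_counts()] object, or a list with elements
#'   `tp`, `fp`, `tn`, `fn`.
#' @return Named numeric vector `sensitivity_pct`, `specificity_pct`,
#'   `accuracy_pct` in `[0, 100]` (or `NA` where undefined).
#' @examples
#' sens_spec_acc(list(tp = 9, fn = 1, tn = 5, fp = 5))
#' @export
sens_spec_acc <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("all confusion counts are zero: nothing was compared")
  c(sensitivity_pct = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity_pct = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    accuracy_pct = 100 * (tp + tn) / n)
}

#' Signed and absolute percentage error
#'
#' PE = (reference - algorithm) / reference x 100, APE = |PE|. A negative
#' PE means the algorithm overestimated the quantity, a positive PE an
#' underestimation. Applied to the total time per activity and to
#' postural-transition counts. A zero reference quantity makes the error
#' undefined: `NA` is returned (not an error) and the value is excluded
#' from cohort aggregation.
#'
#' @param ref_quantity,algo_quantity non-negative scalars (seconds of an
#'   activity, or transition counts).
#' @return Named numeric vector `pe_pct`, `ape_pct`.
#' @examples
#' percentage_error(100, 120)  # overestimation: PE -20
#' percentage_error(1, 3)      # PE -200
#' @export
percentage_error <- function(ref_quantity, algo_quantity) {
  stopifnot(is.numeric(ref_quantity), length(ref_quantity) == 1L,
            is.numeric(algo_quantity), length(algo_quantity) == 1L,
            ref_quantity >= 0, algo_quantity >= 0)
  if (ref_quantity == 0) return(c(pe_pct = NA_real_, ape_pct = NA_real_))
  pe <- (ref_quantity - algo_quantity) / ref_quantity * 100
  c(pe_pct = pe, ape_pct = abs(pe))
}

#' Total-activity percentage error over all classes
#'
#' The total error sums the per-activity time errors before normalizing by
#' the total reference time (a time-weighted total rather than a sum of
#' per-activity percentages):
#' total PE = sum(ref_a - algo_a) / sum(ref_a) x 100 and
#' total APE = sum(|ref_a - algo_a|) / sum(ref_a) x 100.
#' When algorithm and reference label the same window grid their total
#' times coincide, so total PE is identically zero and total APE measures
#' pure misclassification volume.
#'
#' @param ref_times,algo_times numeric vectors of per-activity totals
#'   (seconds), aligned by position.
#' @return Named numeric vector `pe_pct`, `ape_pct` (`NA` if the total
#'   reference time is zero).
#' @examples
#' total_error(c(100, 50, 50), c(110, 50, 40))  # PE 0, APE 10
#' @export
total_error <- function(ref_times, algo_times) {
  stopifnot(is.numeric(ref_times), is.numeric(algo_times),
            length(ref_times) == length(algo_times))
  tot <- sum(ref_times)
  if (tot == 0) return(c(pe_pct = NA_real_, ape_pct = NA_real_))
  c(pe_pct = sum(ref_times - algo_times) / tot * 100,
    ape_pct = sum(abs(ref_times - algo_times)) / tot * 100)
}

#' Per-subject performance report
#'
#' Windowizes the reference events onto the algorithm's grid and computes
#' the full metric suite: for each activity class, for the pooled total
#' (element-wise sum of the three one-vs-rest confusion matrices) and for
#' postural transitions, the confusion counts, sensitivity, specificity,
#' accuracy, and signed/absolute percentage error. Time errors compare the
#' windowized total time per activity; the transition error compares
#' transition counts.
#'
#' @param algo algorithm label series (data frame or character vector).
#' @param ref a [reference_events()] table covering the same period.
#' @param ws_seconds window size of the shared grid.
#' @param subject_id identifier; defaults to the `subject_id` attribute of
#'   `algo` if present.
#' @return Data frame of class `performance_report`, one row per activity
#'   in `c("sedentary", "standing", "dynamic", "total", "transitions")`,
#'   with confusion counts, the three accuracy metrics, reference/algorithm
#'   times (s) or transition counts, and `pe_pct`/`ape_pct`.
#' @export
subject_report <- function(algo, ref, ws_seconds, subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- attr(algo, "subject_id")
    if (is.null(subject_id)) subject_id <- "subject"
  }
  a <- as_labels(algo)
  refw <- windowize_reference(ref, ws_seconds, length(a))
  r <- refw$label

  rows <- vector("list", 5L)
  cms <- lapply(ACTIVITY_LEVELS, function(cls) confusion_counts(a, r, cls))
  names(cms) <- ACTIVITY_LEVELS
  for (i in seq_along(ACTIVITY_LEVELS)) {
    cls <- ACTIVITY_LEVELS[i]
    cm <- cms[[cls]]
    ssa <- sens_spec_acc(cm)
    rt <- sum(r == cls) * ws_seconds
    at <- sum(a == cls) * ws_seconds
    err <- percentage_error(rt, at)
    rows[[i]] <- data.frame(
      subject_id = subject_id, activity = cls,
      tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
      sensitivity_pct = ssa[["sensitivity_pct"]],
      specificity_pct = ssa[["specificity_pct"]],
      accuracy_pct = ssa[["accuracy_pct"]],
      reference_time_s = rt, algorithm_time_s = at,
      reference_count = NA_real_, algorithm_count = NA_real_,
      pe_pct = err[["pe_pct"]], ape_pct = err[["ape_pct"]])
  }

  tot <- list(tp = sum(vapply(cms, `[[`, 0, "tp")),
              fp = sum(vapply(cms, `[[`, 0, "fp")),
              tn = sum(vapply(cms, `[[`, 0, "tn")),
              fn = sum(vapply(cms, `[[`, 0, "fn")))
  ssa <- sens_spec_acc(tot)
  ref_times <- vapply(ACTIVITY_LEVELS, function(cls) sum(r == cls), 0) * ws_seconds
  algo_times <- vapply(ACTIVITY_LEVELS, function(cls) sum(a == cls), 0) * ws_seconds
  terr <- total_error(ref_times, algo_times)
  rows[[4L]] <- data.frame(
    subject_id = subject_id, activity = "total",
    tp = tot$tp, fp = tot$fp, tn = tot$tn, fn = tot$fn,
    sensitivity_pct = ssa[["sensitivity_pct"]],
    specificity_pct = ssa[["specificity_pct"]],
    accuracy_pct = ssa[["accuracy_pct"]],
    reference_time_s = sum(ref_times), algorithm_time_s = sum(algo_times),
    reference_count = NA_real_, algorithm_count = NA_real_,
    pe_pct = terr[["pe_pct"]], ape_pct = terr[["ape_pct"]])

  cmt <- confusion_counts(a, r, "transition")
  nr <- detect_transitions(r)$count
  na <- detect_transitions(a)$count
  ssa <- if (cmt$tp + cmt$fp + cmt$tn + cmt$fn > 0) {
    sens_spec_acc(cmt)
  } else {
    c(sensitivity_pct = NA_real_, specificity_pct = NA_real_,
      accuracy_pct = NA_real_)
  }
  err <- percentage_error(nr, na)
  rows[[5L]] <- data.frame(
    subject_id = subject_id, activity = "transitions",
    tp = cmt$tp, fp = cmt$fp, tn = cmt$tn, fn = cmt$fn,
    sensitivity_pct = ssa[["sensitivity_pct"]],
    specificity_pct = ssa[["specificity_pct"]],
    accuracy_pct = ssa[["accuracy_pct"]],
    reference_time_s = NA_real_, algorithm_time_s = NA_real_,
    reference_count = nr, algorithm_count = na,
    pe_pct = err[["pe_pct"]], ape_pct = err[["ape_pct"]])

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("performance_report", "data.frame")
  out
}

#' Cohort aggregation of performance reports
#'
#' Aggregates per-subject reports to medians with first and third quartiles
#' (linear-interpolation quantiles, `stats::quantile()` type 7), per
#' activity and metric, over the subjects for which the metric is defined
#' (undefined values -- zero reference time or zero reference transitions
#' -- are excluded, not imputed). Each aggregated metric is flagged against
#' the conventional acceptability limits for activity-monitor validation:
#' sensitivity, specificity and accuracy of 80% or higher; PE within
#' plus-or-minus 10%; APE below 10%.
#'
#' @param reports a list of [subject_report()] data frames, or a single
#'   row-bound data frame of them.
#' @return Data frame of class `cohort_summary` with columns `activity`,
#'   `metric`, `median`, `q1`, `q3`, `n_subjects`, `acceptable`.
#' @export
cohort_summary <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  if (length(reports) == 0L) stop("no reports to aggregate")
  all <- do.call(rbind, lapply(reports, as.data.frame))
  metrics <- c("sensitivity_pct", "specificity_pct", "accuracy_pct",
               "pe_pct", "ape_pct")
  acts <- c(ACTIVITY_LEVELS, "total", "transitions")
  out <- list()
  for (act in acts) {
    sub <- all[all$activity == act, , drop = FALSE]
    for (m in metrics) {
      vals <- sub[[m]]
      vals <- vals[!is.na(vals)]
      n <- length(vals)
      if (n > 0L) {
        q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      } else {
        q <- rep(NA_real_, 3L)
      }
      acc <- if (n == 0L) {
        NA
      } else if (m == "pe_pct") {
        abs(q[2L]) <= 10
      } else if (m == "ape_pct") {
        q[2L] < 10
      } else {
        q[2L] >= 80
      }
      out[[length(out) + 1L]] <- data.frame(
        activity = act, metric = m,
        median = q[2L], q1 = q[1L], q3 = q[3L],
        n_subjects = n, acceptable = acc)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cohort_summary", "data.frame")
  res
}
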