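# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (and the signal package): straight-line loops only.

# Direct difference-equation IIR filter: y[n] = sum(b*x) - sum(a[-1]*y).
oracle_iir <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b); na <- length(a)
  y <- numeric(length(x))
  for (n in seq_along(x)) {
    acc <- 0
    for (k in seq_len(nb)) {
      if (n - k + 1 >= 1) acc <- acc + b[k] * x[n - k + 1]
    }
    if (na > 1) {
      for (k in 2:na) {
        if (n - k + 1 >= 1) acc <- acc - a[k] * y[n - k + 1]
      }
    }
    y[n] <- acc
  }
  y
}

# Zero-phase filter exactly as signal::filtfilt applies it: pad the tail
# with 2*max(length(a), length(b)) zeros, run forward, run reversed, trim.
oracle_filtfilt <- function(b, a, x) {
  pad <- c(x, numeric(2 * max(length(a), length(b))))
  y <- oracle_iir(b, a, pad)
  y <- rev(oracle_iir(b, a, rev(y)))
  y[seq_along(x)]
}

# Counts of one window by direct convolution-free recomputation.
oracle_counts <- function(axes, fs, ws, b, a, mode) {
  n_per <- round(ws * fs)
  filtered <- apply(axes, 2, function(v) oracle_filtfilt(b, a, v - mean(v)))
  rect <- if (mode == "single_axis") abs(filtered[, 2]) else
    rowSums(abs(filtered))
  n_win <- floor(nrow(axes) / n_per)
  vapply(seq_len(n_win), function(w) {
    idx <- ((w - 1) * n_per + 1):(w * n_per)
    sum(rect[idx]) / (n_per / fs)
  }, 0)
}

# Element-by-element one-vs-rest confusion counting.
oracle_confusion <- function(algo, ref, target) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(algo)) {
    a <- algo[i] == target
    r <- ref[i] == target
    if (a && r) tp <- tp + 1L
    else if (a && !r) fp <- fp + 1L
    else if (!a && !r) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Adjacent-pair scan for sedentary-to-upright transitions.
oracle_transition_count <- function(labels) {
  cnt <- 0L
  if (length(labels) >= 2) {
    for (i in 2:length(labels)) {
      if (labels[i - 1] == "sedentary" && labels[i] != "sedentary") cnt <- cnt + 1L
    }
  }
  cnt
}

oracle_transition_flags <- function(labels) {
  if (length(labels) < 2) return(integer(0))
  vapply(2:length(labels), function(i) {
    as.integer(labels[i - 1] == "sedentary" && labels[i] != "sedentary")
  }, 0L)
}

# Type-7 quantile by hand from sorted order statistics.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

random_labels <- function(n) {
  sample(c("sedentary", "standing", "dynamic"), n, replace = TRUE)
}

# Reference events built from a label series (one event per run of equal
# labels) on a given window size.
events_from_labels <- function(labels, ws) {
  r <- rle(labels)
  ends <- cumsum(r$lengths) * ws
  reference_events(r$values, c(0, ends[-length(ends)]), ends)
}

# A small deterministic recording: still sedentary -> still standing.
still_recording <- function(n_sed = 250, n_stand = 250, fs = 25) {
  accel_recording(cbind(ax = c(rep(0, n_sed), rep(1, n_stand)),
                        ay = c(rep(1, n_sed), rep(0, n_stand)),
                        az = 0),
                  sample_rate_hz = fs)
}

# Feature frame straight from vectors, for classifier tests.
feature_frame <- function(orientation, counts, ws = 4) {
  n <- length(orientation)
  data.frame(window = seq_len(n), start_s = (seq_len(n) - 1) * ws,
             end_s = seq_len(n) * ws,
             orientation_g = orientation, counts_cps = counts)
}
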