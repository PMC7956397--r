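#' Construct and validate a reference event table
#'
#' Reference annotations (the stand-in for video-observation output) are an
#' ordered sequence of labelled intervals that must tile the measurement
#' period: offsets strictly increase and each event's offset equals the next
#' event's onset. Labels come from the closed three-class vocabulary.
#'
#' @param label character vector of activity labels.
#' @param onset_s,offset_s numeric vectors of event start/end times in
#'   seconds from recording start.
#' @return Data frame of class `reference_events` with columns `label`,
#'   `onset_s`, `offset_s`.
#' @examples
#' reference_events(c("sedentary", "dynamic"), c(0, 60), c(60, 120))
#' @export
reference_events <- function(label, onset_s, offset_s) {
  label <- as_labels(label)
  stopifnot(is.numeric(onset_s), is.numeric(offset_s),
            length(label) == length(onset_s),
            length(label) == length(offset_s),
            length(label) >= 1L)
  if (any(offset_s <= onset_s)) {
    k <- which(offset_s <= onset_s)[1L]
    stop(sprintf("event %d has non-positive duration: [%g, %g)",
                 k, onset_s[k], offset_s[k]))
  }
  n <- length(label)
  if (n > 1L) {
    gap <- which(abs(onset_s[-1L] - offset_s[-n]) > 1e-9)
    if (length(gap) > 0L) {
      k <- gap[1L]
      stop(sprintf(
        "events %d and %d do not tile the period: [%g, %g) then [%g, %g)",
        k, k + 1L, onset_s[k], offset_s[k], onset_s[k + 1L], offset_s[k + 1L]))
    }
  }
  structure(data.frame(label = label, onset_s = as.numeric(onset_s),
                       offset_s = as.numeric(offset_s)),
            class = c("reference_events", "data.frame"))
}

#' Windowize reference events onto the classifier's window grid
#'
#' Segments the reference annotations into the same windows used by the
#' algorithm and assigns each window the main activity within it: the label
#' occupying the greatest total duration inside the window. When two labels
#' tie exactly, the tie breaks toward the later-starting event, so an exact
#' half-half split at a transition goes to the incoming activity. The events
#' must cover the full span `[0, n_windows * ws_seconds)`.
#'
#' @param events a [reference_events()] table.
#' @param ws_seconds window size in seconds.
#' @param n_windows number of windows on the grid (from the paired
#'   recording's [segment_windows()]).
#' @return Label data frame `window`, `start_s`, `end_s`, `label`, aligned
#'   to the algorithm's grid.
#' @export
windowize_reference <- function(events, ws_seconds, n_windows) {
  if (!inherits(events, "reference_events")) {
    events <- reference_events(events$label, events$onset_s, events$offset_s)
  }
  stopifnot(is.numeric(ws_seconds), length(ws_seconds) == 1L, ws_seconds > 0,
            is.numeric(n_windows), length(n_windows) == 1L, n_windows >= 1)
  span <- n_windows * ws_seconds
  if (events$onset_s[1L] > 1e-9 ||
      events$offset_s[nrow(events)] < span - 1e-9) {
    stop(sprintf(
      "reference events cover [%g, %g) but the window grid needs [0, %g)",
      events$onset_s[1L], events$offset_s[nrow(events)], span))
  }
  labs <- character(n_windows)
  for (w in seq_len(n_windows)) {
    s <- (w - 1) * ws_seconds
    e <- w * ws_seconds
    ov <- pmin(events$offset_s, e) - pmax(events$onset_s, s)
    keep <- ov > 1e-12
    dur <- tapply(ov[keep], events$label[keep], sum)
    top <- names(dur)[dur >= max(dur) - 1e-9]
    if (length(top) == 1L) {
      labs[w] <- top
    } else {
      # tie: the later-starting contributing event wins
      cand <- events[keep & events$label %in% top, ]
      labs[w] <- cand$label[which.max(cand$onset_s)]
    }
  }
  idx <- seq_len(n_windows)
  data.frame(window = idx,
             start_s = (idx - 1) * ws_seconds,
             end_s = idx * ws_seconds,
             label = labs)
}
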