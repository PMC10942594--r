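#' Detect population bursts in a rate series
#'
#' A burst is a contiguous suprathreshold excursion of the instantaneous
#' population rate; excursions separated by less than `min_gap_ms` of
#' subthreshold time are merged.  Used to count stimulation-evoked bursts
#' and their timing (e.g. the CAN-current rebound that follows a single
#' pulse by roughly 200 ms).
#'
#' @param rate a [binned_rate()] series (or any data frame with `time_ms`
#'   and `rate_hz`).
#' @param threshold_hz rate threshold defining a burst (default 5).
#' @param min_gap_ms minimal subthreshold gap separating bursts (default
#'   20).
#' @return data frame with one row per burst: `onset_ms`, `offset_ms`,
#'   `peak_ms`, `peak_hz`.
#' @export
detect_bursts <- function(rate, threshold_hz = 5, min_gap_ms = 20) {
  above <- rate$rate_hz > threshold_hz
  if (!any(above))
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      peak_ms = numeric(0), peak_hz = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge segments separated by a short gap
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      gap <- rate$time_ms[seg$start[i]] - rate$time_ms[merged$end[nrow(merged)]]
      if (gap < min_gap_ms) merged$end[nrow(merged)] <- seg$end[i]
      else merged <- rbind(merged, seg[i, ])
    }
  }
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    idx <- merged$start[i]:merged$end[i]
    pk <- idx[which.max(rate$rate_hz[idx])]
    data.frame(onset_ms = rate$time_ms[merged$start[i]],
               offset_ms = rate$time_ms[merged$end[i]],
               peak_ms = rate$time_ms[pk], peak_hz = rate$rate_hz[pk])
  }))
  out
}

#' Time for evoked activity to fade after a pulse
#'
#' Measures the interval from a stimulation onset until the population rate
#' falls below `threshold_hz` and stays there for `hold_ms`.
#'
#' @param rate a [binned_rate()] series.
#' @param onset_ms stimulation onset.
#' @param threshold_hz rate threshold (default 2).
#' @param hold_ms required subthreshold holding time (default 200).
#' @return fade time in ms (`NA` if activity never settles within the
#'   series).
#' @export
fade_time <- function(rate, onset_ms, threshold_hz = 2, hold_ms = 200) {
  idx <- which(rate$time_ms >= onset_ms)
  below <- rate$rate_hz[idx] <= threshold_hz
  n_hold <- max(1L, round(hold_ms / diff(rate$time_ms[1:2])))
  run <- 0L
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= n_hold)
      return(rate$time_ms[idx[i - n_hold + 1L]] - onset_ms)
  }
  NA_real_
}
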