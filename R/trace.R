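#' @export
print.theta_trace <- function(x, ...) {
  cat("<theta_trace>\n")
  cat(sprintf("  duration: %.3g s at dt = %.3g ms\n", x$duration_s, x$dt_ms))
  cat(sprintf("  neurons: %d (%d spikes)\n", nrow(x$layout), nrow(x$spikes)))
  byarea <- table(x$layout$area[x$spikes$neuron])
  if (length(byarea))
    cat("  spikes by area:",
        paste(sprintf("%s=%d", names(byarea), as.integer(byarea)),
              collapse = ", "), "\n")
  cat(sprintf("  theta gain: %.3g nA, phase reset %s\n", x$theta_gain_na,
              if (x$reset_on) "on" else "off"))
  if (length(x$stim_onsets_ms))
    cat(sprintf("  stimulation: %d pulse(s), first at %.1f ms\n",
                length(x$stim_onsets_ms), x$stim_onsets_ms[1]))
  invisible(x)
}

#' @export
summary.theta_trace <- function(object, window_ms = NULL, ...) {
  areas <- unique(object$layout$area)
  rows <- do.call(rbind, lapply(areas, function(a) {
    data.frame(area = a,
               exc_rate_hz = tryCatch(population_rate(object, a, "exc", window_ms),
                                      error = function(e) NA_real_),
               inh_rate_hz = tryCatch(population_rate(object, a, "inh", window_ms),
                                      error = function(e) NA_real_))
  }))
  out <- list(rates = rows,
              theta_amplitude = mean(object$series$theta_amplitude),
              duration_s = object$duration_s)
  class(out) <- "summary.theta_trace"
  out
}

#' @export
print.summary.theta_trace <- function(x, ...) {
  cat(sprintf("theta_trace summary (%.3g s)\n", x$duration_s))
  cat(sprintf("mean oscillator synchrony: %.3f\n", x$theta_amplitude))
  print(x$rates, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Raster and theta-drive plot of a simulation trace
#'
#' @param x a `theta_trace`.
#' @param area optional area to restrict the raster to.
#' @param ... passed to [graphics::plot()].
#' @export
plot.theta_trace <- function(x, area = NULL, ...) {
  op <- par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(par(op))
  sp <- x$spikes
  keep <- if (is.null(area)) rep(TRUE, nrow(sp))
          else x$layout$area[sp$neuron] %in% area
  isinh <- x$layout$cell[sp$neuron] == "inh"
  plot(sp$time_ms[keep], sp$neuron[keep], pch = ".", cex = 1.2,
       col = ifelse(isinh[keep], "firebrick", "navy"),
       xlab = "", ylab = "neuron", ...)
  plot(x$series$time_ms, x$series$theta_drive_na, type = "l", col = "darkgreen",
       xlab = "time (ms)", ylab = "theta drive (nA)")
  if (length(x$stim_onsets_ms)) abline(v = x$stim_onsets_ms, col = "grey40")
  invisible(x)
}

#' Export a trace to plain-text files
#'
#' Writes the spike raster and the per-step scalar series as CSV and a small
#' JSON-like manifest (run metadata, seed, stimulation onsets) so a run can
#' be reproduced and re-analysed outside R.
#'
#' @param trace a `theta_trace`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
export_trace <- function(trace, dir, prefix = "trace") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, paste0(prefix, "_spikes.csv"))
  f2 <- file.path(dir, paste0(prefix, "_series.csv"))
  f3 <- file.path(dir, paste0(prefix, "_meta.yaml"))
  write.csv(trace$spikes, f1, row.names = FALSE)
  write.csv(trace$series, f2, row.names = FALSE)
  yaml::write_yaml(list(duration_s = trace$duration_s, dt_ms = trace$dt_ms,
                        seed = trace$seed, theta_gain_na = trace$theta_gain_na,
                        reset_on = trace$reset_on,
                        stim_onsets_ms = as.numeric(trace$stim_onsets_ms),
                        n_neurons = nrow(trace$layout)), f3)
  invisible(c(f1, f2, f3))
}
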