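#' Tuning targets and search grids
#'
#' The tuning procedure adjusts the theta input gain and the inter-area
#' connection strengths so that every excitatory population fires at the
#' target rate (one spike per theta cycle on average) and the collective
#' rhythm oscillates at the driving frequency.  Reference grids: theta gain
#' 0-0.5 nA in steps of 0.01, wide-range connection gains 0-20 in steps of
#' 0.1, narrow-range gains 0-5 in steps of 0.1.  Coarser grids can be
#' supplied for desk-scale runs.
#'
#' @param target_exc_rate_hz target mean excitatory rate (default 6 Hz).
#' @param target_osc_hz target oscillation frequency (default 6 Hz).
#' @param gain_grid_na grid for the theta gain (nA).
#' @param wide_grid grid for the EC-to-DG connection strength.
#' @param narrow_grid grid for the remaining connection strengths.
#' @return a list of class `tuning_targets`.
#' @export
tuning_targets <- function(target_exc_rate_hz = 6, target_osc_hz = 6,
                           gain_grid_na = seq(0, 0.5, by = 0.01),
                           wide_grid = seq(0, 20, by = 0.1),
                           narrow_grid = seq(0, 5, by = 0.1)) {
  if (!length(gain_grid_na) || !length(wide_grid) || !length(narrow_grid))
    .stopf("tuning grids must be non-empty")
  if (any(diff(gain_grid_na) <= 0) || any(diff(wide_grid) <= 0) ||
      any(diff(narrow_grid) <= 0))
    .stopf("tuning grids must be strictly increasing")
  structure(list(target_exc_rate_hz = target_exc_rate_hz,
                 target_osc_hz = target_osc_hz,
                 gain_grid_na = gain_grid_na, wide_grid = wide_grid,
                 narrow_grid = narrow_grid),
            class = "tuning_targets")
}

#' Distance of measured rates from the tuning targets
#'
#' Euclidean distance in (excitatory rate, oscillation frequency) space,
#' \eqn{J = \sqrt{(f_{exc}-f_{exc,targ})^2 + (f_{osc}-f_{osc,targ})^2}}.
#'
#' @param f_exc_hz measured mean excitatory rate.
#' @param f_osc_hz measured oscillation frequency.
#' @param targets a [tuning_targets()].
#' @return non-negative distance.
#' @export
tuning_metric <- function(f_exc_hz, f_osc_hz, targets = tuning_targets()) {
  if (any(c(f_exc_hz, f_osc_hz) < 0)) .stopf("rates must be >= 0")
  sqrt((f_exc_hz - targets$target_exc_rate_hz)^2 +
       (f_osc_hz - targets$target_osc_hz)^2)
}

#' Mean rate and oscillation frequency of a trace
#'
#' The excitatory rate counts spikes of the selected population over the
#' analysis window; the oscillation frequency is the mean of the inverse
#' intervals between consecutive theta peaks (upward zero crossings of the
#' wrapped theta phase) within the window.
#'
#' @param trace a `theta_trace`.
#' @param area area whose excitatory rate is measured.
#' @param window_ms analysis window `c(from, to)`; default the last second.
#' @param theta_phase optional phase series overriding the trace series
#'   (used when the drive is an external sinusoid).
#' @return list with `f_exc_hz` and `f_osc_hz` (`f_osc_hz` is `NA` with
#'   fewer than two theta peaks).
#' @export
measure_rates <- function(trace, area = "EC", window_ms = NULL,
                          theta_phase = NULL) {
  dur <- trace$duration_s * 1000
  if (is.null(window_ms)) window_ms <- c(dur - 1000, dur)
  if (window_ms[1] < 0 || window_ms[2] > dur) .stopf("window outside trace")
  f_exc <- population_rate(trace, area = area, cell = "exc",
                           window_ms = window_ms)
  ph <- if (is.null(theta_phase)) trace$series$theta_phase else theta_phase
  tt <- trace$series$time_ms
  keep <- tt >= window_ms[1] & tt < window_ms[2]
  ph <- ph[keep]; tt <- tt[keep]
  # theta peak = upward crossing of phase 0
  cross <- which(ph[-1] >= 0 & ph[-length(ph)] < 0 &
                 (ph[-1] - ph[-length(ph)]) < pi)
  peaks <- tt[cross + 1L]
  f_osc <- if (length(peaks) >= 2) mean(1000 / diff(peaks)) else NA_real_
  list(f_exc_hz = f_exc, f_osc_hz = f_osc)
}

.grid_search <- function(grid, eval_fn, verbose = FALSE, refine_points = 0,
                         refine_levels = 3, j_good = 0.5) {
  glob <- range(grid)
  all_g <- grid
  all_j <- vapply(grid, eval_fn, numeric(1))
  step <- if (length(grid) > 1) max(diff(grid)) else 0
  if (refine_points > 0 && step > 0) {
    # successive finer passes around the running argmin; recruitment of a
    # population can switch on over a narrow gain window, so one pass over a
    # coarse grid is not guaranteed to see any intermediate rate
    for (lev in seq_len(refine_levels)) {
      if (min(all_j) < j_good) break
      best <- all_g[which(all_j == min(all_j))[1]]
      lo <- max(glob[1], best - step)
      hi <- min(glob[2], best + step)
      fine <- setdiff(round(seq(lo, hi, length.out = refine_points + 2), 9),
                      round(all_g, 9))
      if (!length(fine)) break
      all_g <- c(all_g, fine)
      all_j <- c(all_j, vapply(fine, eval_fn, numeric(1)))
      step <- (hi - lo) / (refine_points + 1)
    }
  }
  ord <- order(all_g)
  all_g <- all_g[ord]; all_j <- all_j[ord]
  best <- which(all_j == min(all_j))[1]   # ties toward the smaller value
  if (verbose)
    message(sprintf("    best %.3g (J = %.3g, %d evaluations)",
                    all_g[best], all_j[best], length(all_g)))
  list(value = all_g[best], j = all_j[best], grid = all_g, js = all_j)
}

#' Sequential tuning of the theta gain and connection strengths
#'
#' Executes the six-step heuristic on a network factory, in the absence of
#' membrane noise:
#' \enumerate{
#'   \item tune the theta gain against the EC excitatory rate with all
#'     inter-area connections removed;
#'   \item tune the EC-to-DG connection strength;
#'   \item jointly tune the (equal) EC-to-CA3 and DG-to-CA3 strengths;
#'   \item jointly tune the (equal) EC-to-CA1 and CA3-to-CA1 strengths;
#'   \item decouple CA1, drive it with a temporary 6 Hz sinusoid tuned to
#'     the target CA1 rate, and tune the CA1-to-EC feedback against the EC
#'     rate;
#'   \item halve the step-5 value, restore the loop, and re-tune the theta
#'     gain.
#' }
#'
#' @param make_network function `(gains)` returning an `hf_network` whose
#'   inter-area gain matrix equals `gains`; called once per candidate.
#' @param targets a [tuning_targets()].
#' @param duration_s simulated seconds per evaluation (default 3; the last
#'   second is analysed).
#' @param seed seed shared by all evaluation runs.
#' @param j_ceiling largest acceptable distance at each step; exceeding it
#'   raises a tuning-failure error.
#' @param refine_points number of extra evaluations placed around the
#'   coarse argmin of every grid search (0 = plain single-pass search; use
#'   a few points with coarse desk-scale grids).
#' @param verbose print per-step progress.
#' @return a list of class `tuned_gains`: `theta_gain_na`, the tuned
#'   `inter_gain` matrix, the per-step grid/J landscapes (`landscape`), and
#'   the final distance.
#' @export
tune_gains <- function(make_network, targets = tuning_targets(),
                       duration_s = 3, seed = 1L, j_ceiling = 5,
                       refine_points = 0, verbose = FALSE) {
  zero <- wiring_defaults()$inter_gain
  zero[] <- 0
  window <- c(duration_s * 1000 - 1000, duration_s * 1000)
  landscape <- list()

  eval_rates <- function(net, gain_na, area, ext = NULL) {
    tr <- run_simulation(net, duration_s, ext = ext, seed = seed,
                         theta_gain_na = gain_na, noise = FALSE)
    measure_rates(tr, area = area, window_ms = window)
  }
  j_of <- function(mr) {
    f_osc <- if (is.na(mr$f_osc_hz)) 0 else mr$f_osc_hz
    tuning_metric(mr$f_exc_hz, f_osc, targets)
  }

  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  # step 1: theta gain against EC, fully uncoupled
  say("step 1: theta gain (uncoupled EC)")
  net0 <- make_network(zero)
  s1 <- .grid_search(targets$gain_grid_na,
                     function(g) j_of(eval_rates(net0, g, "EC")), verbose,
                     refine_points)
  g_theta <- s1$value
  landscape$step1 <- s1
  if (s1$j > j_ceiling)
    .stopf("tuning failure at step 1: best J = %.2f exceeds ceiling %.2f",
           s1$j, j_ceiling)

  gains <- zero
  # step 2: EC -> DG
  say("step 2: EC->DG")
  s2 <- .grid_search(targets$wide_grid, function(a) {
    gg <- gains; gg["EC", "DG"] <- a
    j_of(eval_rates(make_network(gg), g_theta, "DG"))
  }, verbose, refine_points)
  gains["EC", "DG"] <- s2$value
  landscape$step2 <- s2
  if (s2$j > j_ceiling)
    .stopf("tuning failure at step 2: best J = %.2f exceeds ceiling %.2f",
           s2$j, j_ceiling)

  # step 3: (EC, DG) -> CA3, equal contributions
  say("step 3: (EC,DG)->CA3")
  s3 <- .grid_search(targets$narrow_grid, function(a) {
    gg <- gains; gg["EC", "CA3"] <- a; gg["DG", "CA3"] <- a
    j_of(eval_rates(make_network(gg), g_theta, "CA3"))
  }, verbose, refine_points)
  gains["EC", "CA3"] <- gains["DG", "CA3"] <- s3$value
  landscape$step3 <- s3
  if (s3$j > j_ceiling)
    .stopf("tuning failure at step 3: best J = %.2f exceeds ceiling %.2f",
           s3$j, j_ceiling)

  # step 4: (EC, CA3) -> CA1, equal contributions
  say("step 4: (EC,CA3)->CA1")
  s4 <- .grid_search(targets$narrow_grid, function(a) {
    gg <- gains; gg["EC", "CA1"] <- a; gg["CA3", "CA1"] <- a
    j_of(eval_rates(make_network(gg), g_theta, "CA1"))
  }, verbose, refine_points)
  gains["EC", "CA1"] <- gains["CA3", "CA1"] <- s4$value
  landscape$step4 <- s4
  if (s4$j > j_ceiling)
    .stopf("tuning failure at step 4: best J = %.2f exceeds ceiling %.2f",
           s4$j, j_ceiling)

  # step 5: CA1 decoupled, driven by a temporary sinusoid at the target
  # frequency; first match the CA1 rate, then tune CA1 -> EC feedback.
  say("step 5: CA1->EC under temporary sinusoidal drive")
  net_iso <- make_network(zero)
  ca1 <- which(net_iso$layout$area == "CA1")
  n_steps <- round(duration_s * 1000 / net_iso$config$dt_ms)
  tgrid <- (seq_len(n_steps) - 1) * net_iso$config$dt_ms * 1e-3
  sine <- (1 + cos(2 * pi * targets$target_osc_hz * tgrid)) / 2
  sine_phase <- .wrap_pi(2 * pi * targets$target_osc_hz * tgrid)
  ca1_rate_j <- function(amp) {
    ext <- list(current_na = matrix(amp * sine, ncol = 1), groups = list(ca1))
    tr <- run_simulation(net_iso, duration_s, ext = ext, seed = seed,
                         theta_gain_na = 0, noise = FALSE)
    mr <- measure_rates(tr, "CA1", window, theta_phase = sine_phase)
    j_of(mr)
  }
  s5a <- .grid_search(targets$gain_grid_na, ca1_rate_j, verbose,
                      refine_points)
  amp_ca1 <- s5a$value
  landscape$step5_drive <- s5a

  ext_ca1 <- list(current_na = matrix(amp_ca1 * sine, ncol = 1),
                  groups = list(ca1))
  s5 <- .grid_search(targets$narrow_grid, function(a) {
    gg <- zero; gg["CA1", "EC"] <- a
    tr <- run_simulation(make_network(gg), duration_s, ext = ext_ca1,
                         seed = seed, theta_gain_na = 0, noise = FALSE)
    mr <- measure_rates(tr, "EC", window, theta_phase = sine_phase)
    j_of(mr)
  }, verbose, refine_points)
  landscape$step5 <- s5
  if (s5$j > j_ceiling)
    .stopf("tuning failure at step 5: best J = %.2f exceeds ceiling %.2f",
           s5$j, j_ceiling)

  # step 6: halve the feedback, restore the loop, re-tune the theta gain
  say("step 6: halve CA1->EC, retune theta gain")
  gains["CA1", "EC"] <- s5$value / 2
  net_full <- make_network(gains)
  s6 <- .grid_search(targets$gain_grid_na,
                     function(g) j_of(eval_rates(net_full, g, "EC")), verbose,
                     refine_points)
  g_theta <- s6$value
  landscape$step6 <- s6
  if (s6$j > j_ceiling)
    .stopf("tuning failure at step 6: best J = %.2f exceeds ceiling %.2f",
           s6$j, j_ceiling)

  structure(list(theta_gain_na = g_theta, inter_gain = gains,
                 landscape = landscape, final_j = s6$j,
                 targets = targets, seed = seed, duration_s = duration_s),
            class = "tuned_gains")
}

#' @export
print.tuned_gains <- function(x, ...) {
  cat("tuned gains:\n")
  cat(sprintf("  theta gain: %.3g nA (final J = %.2f)\n", x$theta_gain_na,
              x$final_j))
  nz <- which(x$inter_gain > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz)))
    cat(sprintf("  %s -> %s: %.3g\n", rownames(x$inter_gain)[nz[k, 1]],
                colnames(x$inter_gain)[nz[k, 2]], x$inter_gain[nz[k, 1], nz[k, 2]]))
  invisible(x)
}
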