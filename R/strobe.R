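#' Stroboscopic sampling at positive cup-position peaks
#'
#' Samples the force and ball states once per cycle at every positive
#' maximum of the cup position (a Poincare section of the driven system;
#' minima are not strobed). For trajectories generated from a strategy the
#' peak times are known analytically (`t = k / f`, including the peak at
#' `t = 0` and, when the duration is a whole number of periods, the final
#' one); for other trajectories the peaks are detected numerically with
#' [detect_cycle_peaks()].
#'
#' @param trajectory A `"cup_trajectory"`.
#' @param nominal_f Nominal cycle frequency used for numeric peak detection
#'   when the trajectory carries no strategy.
#' @return An object of class `"strobe_series"`: a list with `peak_times`
#'   (s), `force_at_peak` (N), `ball_ang_at_peak` (rad),
#'   `ball_angvel_at_peak` (rad/s), `cycle_period` (s, one shorter) and
#'   `cycle_amplitude_pp` (m, one shorter; peak-to-trough excursion of each
#'   cycle).
#' @examples
#' tr <- simulate_strategy(strategy(0.1, 1, theta0 = 1), duration = 10)
#' st <- strobe_at_cup_peaks(tr)
#' var(st$force_at_peak)  # ~0: period-1 strategy
#' @export
strobe_at_cup_peaks <- function(trajectory, nominal_f = 1) {
  stopifnot(inherits(trajectory, "cup_trajectory"))
  s <- attr(trajectory, "strategy")
  tt <- trajectory$time
  dur <- tt[length(tt)] - tt[1L]
  if (!is.null(s)) {
    if (dur < 2 / s$frequency - 1e-9) stop("need at least 2 cup-position peaks")
    pk_times <- seq(0, dur + 1e-9, by = 1 / s$frequency)
    pk_times <- pk_times[pk_times <= dur + 1e-9]
    sample_at <- function(ch) {
      stats::approx(tt, trajectory[[ch]], xout = pmin(pk_times, dur))$y
    }
    force <- sample_at("force")
    ball_ang <- sample_at("ball_ang")
    ball_angvel <- sample_at("ball_angvel")
    cyc_amp <- rep(s$amplitude_pp, length(pk_times) - 1L)
  } else {
    pk <- detect_cycle_peaks(trajectory$cup_pos, rate = 1 / mean(diff(tt)),
                             nominal_f = nominal_f)
    if (nrow(pk$maxima) < 2L) stop("need at least 2 cup-position peaks")
    pk_times <- pk$maxima$time + tt[1L]
    sample_at <- function(ch) stats::approx(tt, trajectory[[ch]], xout = pk_times)$y
    force <- sample_at("force")
    ball_ang <- sample_at("ball_ang")
    ball_angvel <- sample_at("ball_angvel")
    cyc_amp <- vapply(seq_len(length(pk_times) - 1L), function(k) {
      in_cycle <- tt >= pk_times[k] & tt <= pk_times[k + 1L]
      max(pk$maxima$value[k], pk$maxima$value[k + 1L]) -
        min(trajectory$cup_pos[in_cycle])
    }, numeric(1))
  }
  structure(list(peak_times = pk_times,
                 force_at_peak = force,
                 ball_ang_at_peak = ball_ang,
                 ball_angvel_at_peak = ball_angvel,
                 cycle_period = diff(pk_times),
                 cycle_amplitude_pp = cyc_amp),
            class = "strobe_series")
}

#' @export
print.strobe_series <- function(x, ...) {
  cat(sprintf("Strobe series: %d cup-position peaks over %.3g s\n",
              length(x$peak_times), diff(range(x$peak_times))))
  cat(sprintf("  strobed force: mean %.3g N, var %.3g N^2, range [%.3g, %.3g] N\n",
              mean(x$force_at_peak), stats::var(x$force_at_peak),
              min(x$force_at_peak), max(x$force_at_peak)))
  invisible(x)
}

#' Bifurcation scan of strobed force over the initial ball angle
#'
#' Simulates one strategy per grid value of the initial ball angle (all
#' other execution variables fixed), strobes the applied force at the cup
#' position peaks, and summarises each strobed-force distribution. The
#' resulting diagram exposes the period-1, quasi-periodic and chaotic
#' regimes of the driven pendulum. Failed grid points are recorded (with a
#' warning naming the angle) rather than aborting the scan.
#'
#' @param theta0_grid Initial ball angles (rad), normally within
#'   `[-pi/2, pi/2]`.
#' @param fixed Named list with `amplitude_pp` (m), `frequency` (Hz) and
#'   `omega0` (rad/s) shared by all grid points.
#' @param params [model_params()].
#' @param duration Simulated seconds per grid point (45 by default, the
#'   experimental trial length).
#' @param rate Output sampling rate (Hz).
#' @param force_model Force convention, see [inverse_dynamics_force()].
#' @return An object of class `"bifurcation_scan"`: list with `theta0`,
#'   `strobes` (list of strobed-force vectors, `NULL` where a point failed),
#'   and `summary` (data frame `theta0`, `n`, `min`, `max`, `var`).
#'   `as.data.frame()` returns the long format (`theta0_rad`, `strobe_index`,
#'   `force_N`).
#' @examples
#' sc <- bifurcation_scan(c(0.4, 1.0), duration = 10)
#' sc$summary
#' @export
bifurcation_scan <- function(theta0_grid,
                             fixed = list(amplitude_pp = 0.1, frequency = 1,
                                          omega0 = 0),
                             params = model_params(), duration = 45,
                             rate = 120, force_model = "rendered") {
  strobes <- vector("list", length(theta0_grid))
  for (k in seq_along(theta0_grid)) {
    st <- tryCatch({
      s <- strategy(fixed$amplitude_pp, fixed$frequency,
                    theta0 = theta0_grid[k], omega0 = fixed$omega0)
      tr <- simulate_strategy(s, params, duration, rate, force_model)
      strobe_at_cup_peaks(tr)$force_at_peak
    }, error = function(e) {
      warning(sprintf("theta0 = %.4g rad failed: %s", theta0_grid[k],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    strobes[k] <- list(st)   # keep NULL placeholders for failed points
  }
  summ <- data.frame(
    theta0 = theta0_grid,
    n = vapply(strobes, length, integer(1)),
    min = vapply(strobes, function(x) if (length(x)) min(x) else NA_real_, 1),
    max = vapply(strobes, function(x) if (length(x)) max(x) else NA_real_, 1),
    var = vapply(strobes, function(x) if (length(x) > 1) stats::var(x) else NA_real_, 1))
  structure(list(theta0 = theta0_grid, strobes = strobes, summary = summ,
                 fixed = fixed),
            class = "bifurcation_scan")
}

#' @export
as.data.frame.bifurcation_scan <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$theta0), function(k) {
    f <- x$strobes[[k]]
    if (!length(f)) return(NULL)
    data.frame(theta0_rad = x$theta0[k], strobe_index = seq_along(f),
               force_N = f)
  }))
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat(sprintf("Bifurcation scan over %d initial ball angles (A = %.3g m pp, f = %.3g Hz)\n",
              length(x$theta0), x$fixed$amplitude_pp, x$fixed$frequency))
  print(utils::head(x$summary, 10))
  if (length(x$theta0) > 10) cat("  ...\n")
  invisible(x)
}
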