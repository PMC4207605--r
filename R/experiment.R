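#' Construct an experimental-style trial record
#'
#' One 45 s manipulation trial sampled at a uniform rate: applied force, cup
#' position and ball angle, optionally cup velocity and ball angular
#' velocity (derivable channels), plus the metronome beep times (2 Hz, one
#' beep per cup excursion).
#'
#' @param time Sample times (s), uniform grid from 0.
#' @param force Applied force (N).
#' @param cup_pos Cup position (m).
#' @param ball_ang Ball angle (rad), positive for displacement opposite to
#'   positive cup displacement.
#' @param cup_vel,ball_angvel Optional measured derivative channels; when
#'   absent the pipeline derives them by zero-phase low-pass filtering and
#'   finite differences.
#' @param metronome_times Beep times (s), or `NULL`.
#' @param subject_id,trial_index Identifiers.
#' @return An object of class `"trial_record"`.
#' @export
trial_record <- function(time, force, cup_pos, ball_ang,
                         cup_vel = NULL, ball_angvel = NULL,
                         metronome_times = NULL,
                         subject_id = NA_character_, trial_index = NA_integer_) {
  n <- length(time)
  chans <- list(force = force, cup_pos = cup_pos, ball_ang = ball_ang)
  if (!is.null(cup_vel)) chans$cup_vel <- cup_vel
  if (!is.null(ball_angvel)) chans$ball_angvel <- ball_angvel
  if (!all(vapply(chans, length, integer(1)) == n)) {
    stop("all channels must have the same length as time")
  }
  dt <- check_uniform_grid(time)
  dur <- time[n] - time[1L]
  if (dur < 45 - dt / 2) {
    warning(sprintf("trial shorter than 45 s (%.3g s); window statistics may be unreliable", dur))
  }
  structure(c(list(time = time), chans,
              list(metronome_times = metronome_times,
                   rate = 1 / dt, subject_id = subject_id,
                   trial_index = trial_index)),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Trial record: subject %s, trial %s, %.3g s at %.4g Hz\n",
              x$subject_id, x$trial_index,
              x$time[length(x$time)] - x$time[1L], x$rate))
  cat(sprintf("  channels: %s%s\n",
              paste(intersect(c("force", "cup_pos", "cup_vel", "ball_ang",
                                "ball_angvel"), names(x)), collapse = ", "),
              if (length(x$metronome_times)) sprintf("; %d metronome beeps",
                                                     length(x$metronome_times))
              else ""))
  invisible(x)
}

#' Zero-phase filtered derivative of a measured channel
#'
#' Low-pass filters the channel with a zero-phase Butterworth filter
#' (forward-backward), then differentiates by fourth-order central
#' differences. Used to derive velocity channels from measured position
#' recordings.
#'
#' @param x Numeric channel.
#' @param rate Sampling rate (Hz).
#' @param cutoff Filter cutoff (Hz, default 10).
#' @param order Butterworth order (default 4).
#' @return Numeric derivative, same length as `x`.
#' @export
filtered_derivative <- function(x, rate, cutoff = 10, order = 4) {
  fd_derivative(zero_phase_lowpass(x, rate, cutoff, order), 1 / rate)
}

# forward-backward Butterworth with odd-reflection padding: the padded
# signal is continuous in value and slope at the joins, so the filter
# settles before it reaches the data and boundary samples stay usable
zero_phase_lowpass <- function(x, rate, cutoff, order = 4) {
  n <- length(x)
  p <- min(n - 1L, ceiling(2 * rate / cutoff) * 4L)
  padded <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  xs <- signal::filtfilt(bf, padded)
  xs[(p + 1L):(p + n)]
}

#' Estimate per-cycle execution variables from a trial
#'
#' Strobes a trial at every positive cup-position maximum: the per-cycle
#' frequency is the inverse peak-to-peak interval, the per-cycle amplitude
#' the peak-to-trough excursion of that cycle, and the per-cycle ball angle
#' and angular velocity are the ball states at each maximum. Window means
#' are taken over the cycles whose strobe time lies in the closed analysis
#' window (25-45 s by default, skipping early-trial transients).
#'
#' @param trial A [trial_record()].
#' @param window Closed analysis window `(start, end)` in s.
#' @param nominal_f Nominal cycle frequency (Hz) for peak detection.
#' @param cutoff Low-pass cutoff (Hz) for derived velocity channels.
#' @return An object of class `"trial_summary"`: list with `per_cycle` (data
#'   frame `t_peak`, `f_k`, `A_k`, `theta0_k`, `omega0_k`; the last cycle
#'   has `NA` frequency/amplitude), `means` (named `frequency`,
#'   `amplitude_pp`, `theta0`, `omega0`), `n_window_cycles`,
#'   `low_cycle_count` flag, and identifiers.
#' @export
estimate_execution_variables <- function(trial, window = c(25, 45),
                                         nominal_f = 1, cutoff = 10) {
  stopifnot(inherits(trial, "trial_record"))
  pk <- detect_cycle_peaks(trial$cup_pos, trial$rate, nominal_f)
  mx <- pk$maxima; mn <- pk$minima
  t_peak <- mx$time + trial$time[1L]
  n_cyc <- nrow(mx) - 1L
  f_k <- A_k <- rep(NA_real_, nrow(mx))
  f_k[seq_len(n_cyc)] <- 1 / diff(t_peak)
  for (k in seq_len(n_cyc)) {
    trough <- mn$value[mn$time > mx$time[k] & mn$time < mx$time[k + 1L]]
    if (length(trough)) A_k[k] <- mx$value[k] - min(trough)
  }
  angvel <- if (!is.null(trial$ball_angvel)) trial$ball_angvel
            else filtered_derivative(trial$ball_ang, trial$rate, cutoff)
  theta0_k <- stats::approx(trial$time, trial$ball_ang, xout = t_peak)$y
  omega0_k <- stats::approx(trial$time, angvel, xout = t_peak)$y
  in_win <- t_peak >= window[1L] & t_peak <= window[2L]
  n_win <- sum(in_win)
  if (n_win < 5L) {
    warning(sprintf("only %d cycles in the analysis window", n_win))
  }
  means <- c(frequency = mean(f_k[in_win], na.rm = TRUE),
             amplitude_pp = mean(A_k[in_win], na.rm = TRUE),
             theta0 = mean(theta0_k[in_win]),
             omega0 = mean(omega0_k[in_win]))
  structure(list(per_cycle = data.frame(t_peak = t_peak, f_k = f_k, A_k = A_k,
                                        theta0_k = theta0_k,
                                        omega0_k = omega0_k),
                 means = means, window = window,
                 n_window_cycles = n_win, low_cycle_count = n_win < 5L,
                 subject_id = trial$subject_id,
                 trial_index = trial$trial_index),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("Trial summary (subject %s, trial %s): %d window cycles\n",
              x$subject_id, x$trial_index, x$n_window_cycles))
  cat(sprintf("  f = %.4g Hz, A = %.4g m pp, theta0 = %.4g rad, omega0 = %.4g rad/s\n",
              x$means["frequency"], x$means["amplitude_pp"],
              x$means["theta0"], x$means["omega0"]))
  invisible(x)
}

#' Strategy measures from continuous experimental data
#'
#' Evaluates the measure set directly on a recorded trial, characterising
#' the combined behaviour of object and controller: mutual information
#' between the continuous force and a cup phase interpolated linearly from
#' 0 to 2 pi between successive cup-position maxima; mean squared force of
#' the whole continuous force channel; and smoothness (jerk and spectral
#' arc length) of the cycle-averaged profiles, where each cycle is linearly
#' time-normalised to a common number of samples and averaged before the
#' smoothness measures are applied.
#'
#' The channels entering the smoothness measures are zero-phase low-pass
#' filtered first (third derivatives amplify sensor noise); mutual
#' information and mean squared force use the raw force channel.
#'
#' @param trial A [trial_record()].
#' @param nominal_f Nominal cycle frequency (Hz).
#' @param n_cycle_samples Samples per time-normalised cycle (default 120).
#' @param phase_method `"linear"` (piecewise-linear between maxima, default)
#'   or `"hilbert"` (analytic-signal phase of the centred cup position).
#' @param smooth_cutoff Low-pass cutoff (Hz) for the smoothness channels;
#'   `NULL` disables the filtering.
#' @return A `"measure_set"` list (map-dependent entries are `NA`).
#' @export
trial_strategy_measures <- function(trial, nominal_f = 1,
                                    n_cycle_samples = 120,
                                    phase_method = c("linear", "hilbert"),
                                    smooth_cutoff = 10) {
  stopifnot(inherits(trial, "trial_record"))
  phase_method <- match.arg(phase_method)
  pk <- detect_cycle_peaks(trial$cup_pos, trial$rate, nominal_f)
  t_peak <- pk$maxima$time + trial$time[1L]
  span <- trial$time >= t_peak[1L] & trial$time <= t_peak[length(t_peak)]
  if (phase_method == "linear") {
    unwrapped <- stats::approx(t_peak, 2 * pi * (seq_along(t_peak) - 1L),
                               xout = trial$time[span])$y
    phase <- unwrapped %% (2 * pi)
  } else {
    x <- trial$cup_pos[span] - mean(trial$cup_pos[span])
    n <- length(x)
    X <- stats::fft(x)
    hwt <- numeric(n)
    hwt[1L] <- 1
    if (n %% 2 == 0) {
      hwt[n / 2 + 1L] <- 1
      hwt[2:(n / 2)] <- 2
    } else hwt[2:((n + 1L) / 2)] <- 2
    analytic <- stats::fft(X * hwt, inverse = TRUE) / n
    phase <- (Arg(analytic)) %% (2 * pi)
  }
  mi <- mutual_information(trial$force[span], phase)
  msf <- mean_squared_force(trial$force)
  mean_period <- mean(diff(t_peak))
  # each cycle is resampled on n_cycle_samples points including both peak
  # endpoints; dropping the duplicate endpoint leaves one exact period
  rate_eff <- (n_cycle_samples - 1L) / mean_period
  avg_profile <- function(ch) {
    # spline (not linear) resampling: interpolation kinks would dominate a
    # third derivative
    sf <- stats::splinefun(trial$time, ch, method = "fmm")
    cycles <- vapply(seq_len(length(t_peak) - 1L), function(k) {
      sf(seq(t_peak[k], t_peak[k + 1L], length.out = n_cycle_samples))
    }, numeric(n_cycle_samples))
    rowMeans(cycles)[-n_cycle_samples]
  }
  smooth <- function(ch) {
    if (is.null(smooth_cutoff) || smooth_cutoff >= trial$rate / 2) return(ch)
    zero_phase_lowpass(ch, trial$rate, smooth_cutoff)
  }
  # the averaged cycle is periodic: pad it circularly so the jerk stencil
  # covers the full cycle without edge loss
  wrap <- function(q) {
    n <- length(q)
    c(q[(n - 1L):n], q, q[1:2])
  }
  ball_avg <- wrap(avg_profile(smooth(trial$ball_ang)))
  force_avg <- wrap(avg_profile(smooth(trial$force)))
  cup_avg <- wrap(avg_profile(smooth(trial$cup_pos)))
  structure(list(
    mi = mi,
    predictability_index = NA_real_,
    sensitivity = NA_real_,
    gle = NA_real_,
    msf = msf,
    jerk_ball_norm = mean_abs_jerk(ball_avg, rate_eff,
                                   normalization = "cycle_amplitude",
                                   cycle_frequency = 1 / mean_period),
    jerk_ball_raw = mean_abs_jerk(ball_avg, rate_eff, normalized = FALSE),
    jerk_force_raw = mean_abs_jerk(force_avg, rate_eff, normalized = FALSE),
    jerk_cup_raw = mean_abs_jerk(cup_avg, rate_eff, normalized = FALSE),
    sal = spectral_arc_length(ball_avg, rate_eff),
    strobe_var = stats::var(stats::approx(trial$time, trial$force,
                                          xout = t_peak)$y)),
    class = "measure_set")
}

#' Look up simulated strategy measures for an estimated trial strategy
#'
#' Bilinearly interpolates every surface of a result-space map at a trial's
#' mean execution variables (amplitude, ball angle), giving the simulated
#' "object-only" counterparts of the continuous experimental measures.
#' Points outside the map domain are clipped to its boundary (with a
#' warning from the lookup).
#'
#' @param summary A `"trial_summary"` from [estimate_execution_variables()].
#' @param map A `"measure_map"`.
#' @return Named list of interpolated values, one per surface, of class
#'   `"measure_set"`.
#' @export
map_lookup_measures <- function(summary, map) {
  stopifnot(inherits(summary, "trial_summary"), inherits(map, "measure_map"))
  if (!length(map$surfaces)) stop("empty measure map")
  out <- lapply(names(map$surfaces), function(f) {
    map_lookup(map, f, summary$means[["amplitude_pp"]],
               summary$means[["theta0"]])
  })
  structure(stats::setNames(out, names(map$surfaces)), class = "measure_set")
}

#' Early-versus-late practice comparison
#'
#' Compares the first and last `n_edge` trials of each subject by a paired
#' two-sided t-test across subjects, the standard practice-effect contrast
#' for a 50-trial protocol.
#'
#' @param values Data frame with columns `subject`, `trial` and `value`
#'   (one row per trial), covering at least 2 subjects with at least
#'   `2 * n_edge` trials each.
#' @param n_edge Number of edge trials per side (default 5).
#' @return A list of class `"early_late_comparison"`: per-subject means,
#'   early/late group mean and SD, `t`, `df`, `p`, and significance flags at
#'   alpha 0.05 and 0.10.
#' @export
early_late_comparison <- function(values, n_edge = 5) {
  stopifnot(all(c("subject", "trial", "value") %in% names(values)))
  subs <- split(values, values$subject, drop = TRUE)
  if (length(subs) < 2L) stop("need at least 2 subjects")
  per_subject <- do.call(rbind, lapply(subs, function(d) {
    d <- d[order(d$trial), ]
    if (nrow(d) < 2 * n_edge) {
      stop(sprintf("subject %s has fewer than %d trials", d$subject[1L],
                   2 * n_edge))
    }
    data.frame(subject = d$subject[1L],
               early = mean(d$value[seq_len(n_edge)]),
               late = mean(d$value[seq(nrow(d) - n_edge + 1L, nrow(d))]))
  }))
  d <- per_subject$late - per_subject$early
  if (stats::sd(d) == 0) {
    # degenerate paired test: identical differences across subjects
    tt <- list(statistic = c(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf),
               parameter = c(df = length(d) - 1),
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(per_subject$late, per_subject$early, paired = TRUE)
  }
  structure(list(per_subject = per_subject,
                 early_mean = mean(per_subject$early),
                 early_sd = stats::sd(per_subject$early),
                 late_mean = mean(per_subject$late),
                 late_sd = stats::sd(per_subject$late),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 significant_05 = tt$p.value < 0.05,
                 significant_10 = tt$p.value < 0.10),
            class = "early_late_comparison")
}

#' @export
print.early_late_comparison <- function(x, ...) {
  cat(sprintf("Early vs late practice (paired t, %d subjects)\n",
              nrow(x$per_subject)))
  cat(sprintf("  early %.4g +/- %.3g, late %.4g +/- %.3g\n",
              x$early_mean, x$early_sd, x$late_mean, x$late_sd))
  cat(sprintf("  t(%g) = %.3g, p = %.3g%s\n", x$df, x$t, x$p,
              if (x$significant_05) " *" else if (x$significant_10) " ." else ""))
  invisible(x)
}

#' Metronome asynchrony statistics of a trial
#'
#' Matches every metronome beep inside the analysis window to the nearest
#' cup-position extremum (maximum or minimum) and summarises the signed
#' asynchronies (extremum time minus beep time).
#'
#' @param trial A [trial_record()] with `metronome_times`.
#' @param window Closed window (s), default 20-45 s (skipping transients).
#' @param nominal_f Nominal cycle frequency (Hz).
#' @return List with `mean_asynchrony`, `mean_abs_asynchrony`,
#'   `sd_asynchrony` (s) and `n_beeps`.
#' @seealso [asynchrony_amplitude_correlation()] for the across-trial
#'   amplitude relation.
#' @export
asynchrony_stats <- function(trial, window = c(20, 45), nominal_f = 1) {
  stopifnot(inherits(trial, "trial_record"))
  beeps <- trial$metronome_times
  beeps <- beeps[beeps >= window[1L] & beeps <= window[2L]]
  if (!length(beeps)) stop("no metronome beeps in the analysis window")
  pk <- detect_cycle_peaks(trial$cup_pos, trial$rate, nominal_f)
  extrema <- sort(c(pk$maxima$time, pk$minima$time)) + trial$time[1L]
  asyn <- vapply(beeps, function(b) extrema[which.min(abs(extrema - b))] - b,
                 numeric(1))
  list(mean_asynchrony = mean(asyn),
       mean_abs_asynchrony = mean(abs(asyn)),
       sd_asynchrony = stats::sd(asyn),
       n_beeps = length(beeps))
}

#' Correlation of an asynchrony statistic with movement amplitude
#'
#' Pearson correlation (with test) between a per-trial asynchrony summary
#' and the per-trial mean movement amplitude, pooled over trials.
#'
#' @param asynchrony Numeric per-trial asynchrony values (s).
#' @param amplitude Numeric per-trial amplitudes (m), same length.
#' @return `stats::cor.test` result.
#' @export
asynchrony_amplitude_correlation <- function(asynchrony, amplitude) {
  stopifnot(length(asynchrony) == length(amplitude))
  stats::cor.test(asynchrony, amplitude)
}
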