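#' Mutual information between applied force and cup phase
#'
#' Kernel-density estimate of the mutual information
#' `MI = integral p(F, phi) ln[ p(F, phi) / (p(F) p(phi)) ] dF dphi`
#' between a force series and the cup's cycle phase, the package's central
#' predictability measure: a strategy whose force is a repeatable function
#' of the cup phase carries high MI, while cycle-to-cycle wandering of the
#' force-phase relation lowers it.
#'
#' The joint density is a product-Gaussian kernel estimate with per-dimension
#' Silverman rule-of-thumb bandwidths, evaluated on a `n_grid` by `n_grid`
#' grid spanning `[min(F) - 3h, max(F) + 3h]` in force and one full cycle
#' `[0, 2 pi)` in phase. Phase circularity is handled by replicating samples
#' at `phi +/- 2 pi` before estimation so kernel mass wraps around the cycle
#' boundary. Marginals are obtained by numerically integrating the (grid
#' normalised) joint, which makes the estimate a discrete Kullback-Leibler
#' divergence and therefore non-negative. The natural logarithm is used, so
#' the result is in nat. The estimator is deterministic given its inputs.
#'
#' Bandwidth selection accounts for the serial dependence of rhythmic data:
#' within one cycle the force samples are (near-)deterministic functions of
#' the phase, so the independent information enters per cycle, not per
#' sample. The Silverman rule for the force dimension therefore uses the
#' cycle count (inferred from the phase wraps) as the effective sample size,
#' `h_F = 0.9 min(sd, IQR/1.34) n_cycles^(-1/5)`. The phase dimension is a
#' deterministic uniform sweep whose coverage genuinely refines with every
#' sample, so its bandwidth uses the raw sample count.
#'
#' @param force Numeric force samples (N).
#' @param phase Cup phase samples in `[0, 2 pi)` (rad), same length.
#' @param n_grid Grid resolution per dimension (default 128).
#' @param bw Optional length-2 numeric `(h_force, h_phase)` overriding the
#'   default bandwidths.
#' @return Mutual information in nat (scalar, >= 0). A constant force series
#'   has no definable density and returns 0 with a warning.
#' @examples
#' tr <- simulate_strategy(strategy(0.1, 1, theta0 = 1), duration = 20)
#' mutual_information(tr$force, tr$phase)
#' @export
mutual_information <- function(force, phase, n_grid = 128, bw = NULL) {
  stopifnot(length(force) == length(phase))
  ok <- is.finite(force) & is.finite(phase)
  force <- force[ok]; phase <- phase[ok] %% (2 * pi)
  n <- length(force)
  if (n < 10L) stop("too few samples for a density estimate")
  if (stats::sd(force) == 0) {
    warning("constant force series: mutual information set to 0")
    return(0)
  }
  if (is.null(bw)) {
    n_cycles <- max(sum(diff(phase) < -pi) + 1L, 2L)
    hF <- silverman_bw(force, n_cycles)
    hP <- stats::bw.nrd0(phase)
  } else {
    hF <- bw[1L]; hP <- bw[2L]
  }
  # replicate samples near the phase boundary one cycle out on each side
  lo <- phase <= 4 * hP
  hi <- phase >= 2 * pi - 4 * hP
  F3 <- c(force, force[lo], force[hi])
  P3 <- c(phase, phase[lo] + 2 * pi, phase[hi] - 2 * pi)
  Fg <- seq(min(force) - 3 * hF, max(force) + 3 * hF, length.out = n_grid)
  Pg <- seq(0, 2 * pi, length.out = n_grid + 1L)[seq_len(n_grid)]
  KF <- stats::dnorm(outer(Fg, F3, "-") / hF) / hF
  KP <- stats::dnorm(outer(Pg, P3, "-") / hP) / hP
  p <- (KF %*% t(KP)) / n                       # n_grid x n_grid joint
  wF <- trapezoid_weights(Fg)                   # trapezoid in force
  wP <- rep(2 * pi / n_grid, n_grid)            # periodic rectangle in phase
  total <- as.numeric(t(wF) %*% p %*% wP)
  p <- p / total
  pF <- as.numeric(p %*% wP)                    # marginal over phase
  pP <- as.numeric(t(wF) %*% p)                 # marginal over force
  W <- outer(wF, wP)
  ref <- outer(pF, pP)
  pos <- p > .Machine$double.eps & ref > 0
  sum(W[pos] * p[pos] * log(p[pos] / ref[pos]))
}

# Silverman's rule of thumb with an explicit (effective) sample size
silverman_bw <- function(x, n_eff) {
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  0.9 * spread * n_eff^(-1 / 5)
}

trapezoid_weights <- function(grid) {
  h <- diff(grid)
  w <- numeric(length(grid))
  w[1L] <- h[1L] / 2
  w[length(grid)] <- h[length(h)] / 2
  if (length(grid) > 2L) {
    w[2:(length(grid) - 1L)] <- (h[-length(h)] + h[-1L]) / 2
  }
  w
}

#' Predictability index from strobed-force scatter
#'
#' A variance-based companion to [mutual_information()]: one minus the
#' strobed-force variance normalised by a reference variance, clipped to
#' `[0, 1]`. A perfectly repeatable (period-1) strategy has index 1; a
#' strategy whose strobed-force variance reaches the normaliser has index 0.
#' The package's result-space maps normalise by each strategy's own
#' continuous-force variance (relative cycle-to-cycle scatter); the largest
#' strobed-force variance over an evaluated map is an alternative
#' (absolute) convention.
#'
#' @param strobe A `"strobe_series"` from [strobe_at_cup_peaks()] (or a plain
#'   numeric vector of strobed force values).
#' @param normalizer Reference variance (N^2), > 0.
#' @return Dimensionless scalar in `[0, 1]`.
#' @export
predictability_index <- function(strobe, normalizer) {
  f <- if (inherits(strobe, "strobe_series")) strobe$force_at_peak else strobe
  if (length(f) < 5L) stop("need at least 5 strobe samples")
  if (!is.finite(normalizer) || normalizer <= 0) {
    stop("normalizer must be a positive variance")
  }
  min(max(1 - stats::var(f) / normalizer, 0), 1)
}

#' Mean squared force
#'
#' Time-averaged squared applied force over the series, a mechanical-effort
#' proxy in N^2.
#'
#' @param force Numeric force samples (N).
#' @return Scalar N^2.
#' @examples
#' mean_squared_force(sin(2 * pi * seq(0, 1, by = 1 / 120)[-121]))  # 0.5
#' @export
mean_squared_force <- function(force) {
  force <- force[is.finite(force)]
  if (!length(force)) stop("empty force series")
  mean(force^2)
}

#' Mean absolute jerk of a sampled signal
#'
#' Third derivative by central finite differences
#' (`j_i = (s_{i+2} - 2 s_{i+1} + 2 s_{i-1} - s_{i-2}) / (2 h^3)`), averaged
#' in absolute value. Two dimensionless normalisations by a jerk amplitude
#' are offered:
#'
#' * `"peak"`: divide by the trial maximum absolute jerk. Any pure sinusoid,
#'   of any amplitude and frequency, gives `mean|cos| / max|cos| = 2 / pi`.
#' * `"cycle_amplitude"`: divide by the jerk amplitude implied by the
#'   signal's excursion at the nominal cycle frequency,
#'   `(max(s) - min(s)) / 2 * (2 pi f)^3`. A sinusoid at the cycle frequency
#'   again gives `2 / pi`; unlike the peak variant the denominator is not
#'   dominated by isolated jerk spikes, which matters for chaotic ball
#'   trajectories (see the package vignette).
#'
#' Constant signals return 0 under all variants.
#'
#' @param signal Numeric samples (any channel: ball angle, force, cup
#'   position).
#' @param rate Sampling rate (Hz).
#' @param normalized If `TRUE` (default) return the dimensionless normalised
#'   jerk; otherwise the raw mean |jerk| in (signal unit)/s^3.
#' @param normalization `"peak"` (default) or `"cycle_amplitude"`.
#' @param cycle_frequency Nominal cycle frequency (Hz); required for the
#'   `"cycle_amplitude"` normalisation.
#' @return Scalar jerk measure, >= 0.
#' @export
mean_abs_jerk <- function(signal, rate, normalized = TRUE,
                          normalization = c("peak", "cycle_amplitude"),
                          cycle_frequency = NULL) {
  normalization <- match.arg(normalization)
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 5L) stop("need at least 5 samples for a jerk estimate")
  h <- 1 / rate
  i <- 3:(n - 2L)
  jerk <- (signal[i + 2L] - 2 * signal[i + 1L] + 2 * signal[i - 1L] -
             signal[i - 2L]) / (2 * h^3)
  if (!normalized) return(mean(abs(jerk)))
  amp <- if (normalization == "peak") {
    max(abs(jerk))
  } else {
    if (is.null(cycle_frequency)) {
      stop("cycle_frequency is required for the cycle_amplitude normalisation")
    }
    diff(range(signal)) / 2 * (2 * pi * cycle_frequency)^3
  }
  if (amp == 0) return(0)
  mean(abs(jerk)) / amp
}

#' Spectral arc-length smoothness
#'
#' Smoothness as the (negated) arc length of the normalised magnitude
#' spectrum of the signal, following the spectral arc-length convention:
#' the Fourier magnitude spectrum is normalised by its maximum, truncated at
#' an adaptive cutoff (the highest frequency below `cutoff` where the
#' normalised magnitude still exceeds `amp_threshold`), the frequency axis
#' is normalised by that cutoff, and the arc length of the resulting curve
#' is accumulated. Values are always `<= 0`; values closer to zero mean a
#' smoother signal. The measure is invariant to amplitude scaling.
#'
#' @param signal Numeric samples.
#' @param rate Sampling rate (Hz).
#' @param cutoff Maximum cutoff frequency (Hz), default 20.
#' @param amp_threshold Normalised-amplitude threshold for the adaptive
#'   cutoff, default 0.05.
#' @param pad Zero-padding factor for the FFT (default 4).
#' @return Dimensionless scalar `<= 0`.
#' @export
spectral_arc_length <- function(signal, rate, cutoff = 20,
                                amp_threshold = 0.05, pad = 4) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 16L || n < rate / 2) {
    stop("need at least half a second (and 16 samples) of data")
  }
  if (all(signal == 0)) stop("all-zero signal has no spectrum to measure")
  nfft <- 2^ceiling(log2(n * pad))
  V <- Mod(stats::fft(c(signal, rep(0, nfft - n))))
  freqs <- (seq_len(nfft) - 1L) * rate / nfft
  half <- freqs <= rate / 2
  V <- V[half]; freqs <- freqs[half]
  Vn <- V / max(V)
  in_band <- freqs <= cutoff
  above <- which(in_band & Vn >= amp_threshold)
  i_cut <- max(above, 2L)
  f_cut <- freqs[i_cut]
  sel <- seq_len(i_cut)
  df <- diff(freqs[sel]) / f_cut
  dV <- diff(Vn[sel])
  -sum(sqrt(df^2 + dV^2))
}

#' Bundle every strategy measure for one simulated strategy
#'
#' Simulates the strategy and evaluates the full measure set on it:
#' mutual information (force vs cup phase), the predictability index
#' (strobed-force variance relative to the strategy's own continuous-force
#' variance), mean squared force, normalised and raw mean absolute jerk of
#' ball, force and cup channels, spectral arc length of the ball angle,
#' strobed-force variance, and (optionally) the finite-time Lyapunov
#' exponent. MI sensitivity needs map-level context (an MI range) and stays
#' `NA` here; see [mi_sensitivity()].
#'
#' @param s A [strategy()].
#' @param params [model_params()].
#' @param duration Simulated seconds (default 45).
#' @param rate Sampling rate (Hz).
#' @param force_model Force convention.
#' @param gle Also compute the Lyapunov exponent (default `TRUE`).
#' @param gle_duration Horizon for the exponent (s).
#' @return A named list of class `"measure_set"`.
#' @export
strategy_measures <- function(s, params = model_params(), duration = 45,
                              rate = 120, force_model = "rendered",
                              gle = TRUE, gle_duration = 60) {
  tr <- simulate_strategy(s, params, duration, rate, force_model)
  st <- strobe_at_cup_peaks(tr)
  strobe_var <- stats::var(st$force_at_peak)
  force_var <- stats::var(tr$force)
  out <- list(
    mi = mutual_information(tr$force, tr$phase),
    predictability_index = if (force_var > 0)
      predictability_index(st, force_var) else NA_real_,
    sensitivity = NA_real_,
    gle = if (gle) as.numeric(global_lyapunov(s, params,
                                              duration = gle_duration))
          else NA_real_,
    msf = mean_squared_force(tr$force),
    jerk_ball_norm = mean_abs_jerk(tr$ball_ang, rate,
                                   normalization = "cycle_amplitude",
                                   cycle_frequency = s$frequency),
    jerk_ball_raw = mean_abs_jerk(tr$ball_ang, rate, normalized = FALSE),
    jerk_force_raw = mean_abs_jerk(tr$force, rate, normalized = FALSE),
    jerk_cup_raw = mean_abs_jerk(tr$cup_pos, rate, normalized = FALSE),
    sal = spectral_arc_length(tr$ball_ang, rate),
    strobe_var = strobe_var)
  structure(out, class = "measure_set", strategy = s)
}

#' @export
print.measure_set <- function(x, ...) {
  cat("Strategy measures\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm,
                if (is.na(x[[nm]])) "NA" else format(x[[nm]], digits = 4)))
  }
  invisible(x)
}
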