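#' Configuration for a synthetic practice cohort
#'
#' Parameters of the synthetic-subject generator that emulates a motor
#' practice experiment: over `n_trials` trials each subject's target cup
#' amplitude follows an exponential learning curve from `amplitude_start`
#' toward `amplitude_end` (time constant `learning_timescale` trials) with
#' between-subject offsets and trial-to-trial jitter; the ball is started
#' near an anti-phase target angle, except in occasional early-practice
#' "chaotic episodes" where it starts in-phase (negative angle) and the
#' object behaves chaotically; trials are realised by forward simulation
#' under a proportional-derivative tracking of the target sinusoid with
#' white motor noise on the commanded force, and Gaussian sensor noise is
#' added to the recorded kinematic channels.
#'
#' The amplitude defaults (21.45 cm to 28.03 cm peak-to-peak) and the
#' anti-phase ball-angle target (~0.95 rad) describe the practice dynamics
#' the generator emulates; the generator makes no claim about any
#' individual human controller.
#'
#' @param n_subjects,n_trials Cohort size (default 8 subjects, 50 trials).
#' @param trial_duration Trial length (s, default 45).
#' @param rate Recording rate (Hz, default 120).
#' @param amplitude_start,amplitude_end Early/late target peak-to-peak
#'   amplitudes (m).
#' @param theta0_target Anti-phase ball-angle target (rad).
#' @param learning_timescale Exponential learning time constant (trials).
#' @param frequency Cup frequency (Hz); the metronome paces 2 beeps per
#'   cycle.
#' @param motor_noise_sd White motor noise SD on the commanded force (N).
#' @param sensor_noise_pos,sensor_noise_ang Sensor noise SDs on the recorded
#'   cup position (m) and ball angle (rad).
#' @param chaotic_episode_prob_early Probability of a chaotic episode in the
#'   first trial; decays with the learning timescale.
#' @param subject_amp_sd Between-subject amplitude offset SD (m).
#' @param trial_amp_jitter_sd Trial-to-trial amplitude jitter SD (m).
#' @param theta0_jitter_sd Trial-to-trial ball-angle jitter SD (rad).
#' @param seed Cohort seed; seeded runs are reproducible.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 8, n_trials = 50, trial_duration = 45,
                          rate = 120, amplitude_start = 0.2145,
                          amplitude_end = 0.2803, theta0_target = 0.95,
                          learning_timescale = 12, frequency = 1,
                          motor_noise_sd = 1.0, sensor_noise_pos = 0.002,
                          sensor_noise_ang = 0.01,
                          chaotic_episode_prob_early = 0.35,
                          subject_amp_sd = 0.03, trial_amp_jitter_sd = 0.015,
                          theta0_jitter_sd = 0.12, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$chaotic_episode_prob_early < 0 || cfg$chaotic_episode_prob_early > 1) {
    stop("chaotic_episode_prob_early must be in [0, 1]")
  }
  for (nm in c("motor_noise_sd", "sensor_noise_pos", "sensor_noise_ang",
               "subject_amp_sd", "trial_amp_jitter_sd", "theta0_jitter_sd")) {
    if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
  }
  if (cfg$n_subjects < 1 || cfg$n_trials < 1) stop("empty cohort")
  if (cfg$amplitude_start <= 0 || cfg$amplitude_end <= 0 ||
      cfg$learning_timescale <= 0 || cfg$frequency <= 0) {
    stop("amplitudes, timescale and frequency must be positive")
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d subjects x %d trials, %.3g s at %g Hz\n",
              x$n_subjects, x$n_trials, x$trial_duration, x$rate))
  cat(sprintf("  amplitude %.3g -> %.3g m pp (tau = %g trials), theta0 target %.3g rad\n",
              x$amplitude_start, x$amplitude_end, x$learning_timescale,
              x$theta0_target))
  invisible(x)
}

# evaluate expr under a local RNG seed, leaving the caller's RNG untouched;
# the seed argument is forced first so a seed drawn from the caller's stream
# is not rewound by the state restore
with_seed <- function(seed, expr) {
  force(seed)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

subject_seeds <- function(config) {
  with_seed(config$seed, sample.int(.Machine$integer.max - 1L,
                                    config$n_subjects))
}

#' Per-trial target strategy schedule of one synthetic subject
#'
#' The statistical layer of the generator: the per-trial target amplitude
#' (learning curve + subject offset + trial jitter), ball-angle target
#' (anti-phase, or in-phase during chaotic episodes) and the chaotic-episode
#' draws. Exposed separately so cohort-level statistics (learning trends,
#' type-I error of the early/late contrast) can be studied without running
#' the trial dynamics.
#'
#' @param config A [cohort_config()].
#' @param subject_seed Integer seed for this subject's generator.
#' @return Data frame with `trial`, `amplitude_target` (m pp),
#'   `theta0_init` (rad), `chaotic` (logical).
#' @export
strategy_schedule <- function(config, subject_seed) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(subject_seed, {
    k <- seq_len(config$n_trials)
    curve <- config$amplitude_end -
      (config$amplitude_end - config$amplitude_start) *
      exp(-(k - 1) / config$learning_timescale)
    offset <- stats::rnorm(1, 0, config$subject_amp_sd)
    amp <- pmax(curve + offset +
                  stats::rnorm(config$n_trials, 0, config$trial_amp_jitter_sd),
                0.05)
    p_chaos <- config$chaotic_episode_prob_early *
      exp(-(k - 1) / config$learning_timescale)
    chaotic <- stats::runif(config$n_trials) < p_chaos
    th0 <- stats::rnorm(config$n_trials, config$theta0_target,
                        config$theta0_jitter_sd)
    th0[chaotic] <- stats::rnorm(sum(chaotic), -1.1, 0.25)
    data.frame(trial = k, amplitude_target = amp, theta0_init = th0,
               chaotic = chaotic)
  })
}

#' Generate a noiseless trial from a known strategy
#'
#' Runs the prescribed-cup simulation and inverse dynamics for a strategy
#' and packages the result as an experimental-style trial record with
#' metronome beeps at twice the cup frequency, aligned with the cup
#' extrema. Channels satisfy the equations of motion to integrator
#' accuracy, making this the ground-truth input for parameter-recovery
#' tests of the pipeline.
#'
#' @param s A [strategy()].
#' @param params [model_params()].
#' @param duration Trial length (s).
#' @param rate Recording rate (Hz).
#' @param force_model Force convention.
#' @param subject_id,trial_index Identifiers.
#' @return A [trial_record()] with all five channels filled.
#' @examples
#' tr <- generate_clean_trial(strategy(0.25, 1, theta0 = 0.95))
#' length(tr$time)  # 5401 samples for 45 s at 120 Hz
#' @export
generate_clean_trial <- function(s, params = model_params(), duration = 45,
                                 rate = 120, force_model = "rendered",
                                 subject_id = "synthetic",
                                 trial_index = NA_integer_) {
  tr <- simulate_strategy(s, params, duration, rate, force_model)
  trial_record(time = tr$time, force = tr$force, cup_pos = tr$cup_pos,
               ball_ang = tr$ball_ang, cup_vel = tr$cup_vel,
               ball_angvel = tr$ball_angvel,
               metronome_times = seq(0, duration, by = 0.5 / s$frequency),
               subject_id = subject_id, trial_index = trial_index)
}

# PD tracking gains used to realise synthetic trials (plumbing, not a model
# of the human controller): stiff enough for ~2% amplitude fidelity at 1 Hz
pd_gains <- function() c(kp = 6000, kd = 200)

#' Generate the practice trials of one synthetic subject
#'
#' Realises every scheduled trial by forward simulation of the full
#' cart-pendulum under a proportional-derivative tracking of the target
#' sinusoid (fixed-step Runge-Kutta at 8 substeps per recorded frame) with
#' white motor noise held constant within each recorded frame. The
#' simulation starts on the target peak with the scheduled ball angle;
#' Gaussian sensor noise is added to the recorded cup-position and
#' ball-angle channels. All trials of the subject are integrated in one
#' vectorised batch.
#'
#' @param config A [cohort_config()].
#' @param subject_index Subject number (1-based), used for the subject id.
#' @param subject_seed Seed for this subject (defaults to the seed derived
#'   from the cohort seed).
#' @param params [model_params()].
#' @return List with `trials` (list of [trial_record()]) and `schedule`
#'   (the ground-truth [strategy_schedule()]).
#' @export
generate_synthetic_subject <- function(config, subject_index,
                                       subject_seed = subject_seeds(config)[subject_index],
                                       params = model_params()) {
  stopifnot(inherits(config, "cohort_config"))
  sched <- strategy_schedule(config, subject_seed)
  nT <- config$n_trials
  rate <- config$rate
  n_frames <- round(config$trial_duration * rate)
  noise <- with_seed(subject_seed + 1L, {
    list(motor = matrix(stats::rnorm(n_frames * nT, 0, config$motor_noise_sd),
                        n_frames, nT),
         pos = matrix(stats::rnorm((n_frames + 1L) * nT, 0,
                                   config$sensor_noise_pos),
                      n_frames + 1L, nT),
         ang = matrix(stats::rnorm((n_frames + 1L) * nT, 0,
                                   config$sensor_noise_ang),
                      n_frames + 1L, nT))
  })
  m <- params$m_ball; M <- params$m_cup
  l <- params$rod_length; g <- params$gravity
  w <- 2 * pi * config$frequency
  amp <- sched$amplitude_target / 2
  gains <- pd_gains()
  substeps <- 8L
  dt <- 1 / (rate * substeps)
  # batch state across trials
  x <- amp; v <- rep(0, nT)
  th <- sched$theta0_init; om <- rep(0, nT)
  rec <- list(x = matrix(NA_real_, n_frames + 1L, nT),
              th = matrix(NA_real_, n_frames + 1L, nT),
              F = matrix(NA_real_, n_frames + 1L, nT))
  ctrl_force <- function(t, x, v, noise_row) {
    gains["kp"] * (amp * cos(w * t) - x) +
      gains["kd"] * (-amp * w * sin(w * t) - v) + noise_row
  }
  deriv <- function(t, x, v, th, om, Fap) {
    coef <- M + m + m * sin(th)^2
    xdd <- (Fap - m * sin(th) * (g * cos(th) + l * om^2)) / coef
    list(dx = v, dv = xdd, dth = om, dom = (xdd * cos(th) - g * sin(th)) / l)
  }
  rec$x[1L, ] <- x; rec$th[1L, ] <- th
  rec$F[1L, ] <- ctrl_force(0, x, v, noise$motor[1L, ])
  for (fr in seq_len(n_frames)) {
    nz <- noise$motor[fr, ]
    t0 <- (fr - 1L) / rate
    for (ss in seq_len(substeps)) {
      t <- t0 + (ss - 1L) * dt
      F1 <- ctrl_force(t, x, v, nz)
      k1 <- deriv(t, x, v, th, om, F1)
      x2 <- x + dt / 2 * k1$dx; v2 <- v + dt / 2 * k1$dv
      th2 <- th + dt / 2 * k1$dth; om2 <- om + dt / 2 * k1$dom
      F2 <- ctrl_force(t + dt / 2, x2, v2, nz)
      k2 <- deriv(t, x2, v2, th2, om2, F2)
      x3 <- x + dt / 2 * k2$dx; v3 <- v + dt / 2 * k2$dv
      th3 <- th + dt / 2 * k2$dth; om3 <- om + dt / 2 * k2$dom
      F3 <- ctrl_force(t + dt / 2, x3, v3, nz)
      k3 <- deriv(t, x3, v3, th3, om3, F3)
      x4 <- x + dt * k3$dx; v4 <- v + dt * k3$dv
      th4 <- th + dt * k3$dth; om4 <- om + dt * k3$dom
      F4 <- ctrl_force(t + dt, x4, v4, nz)
      k4 <- deriv(t, x4, v4, th4, om4, F4)
      x <- x + dt / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
      v <- v + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
      th <- th + dt / 6 * (k1$dth + 2 * k2$dth + 2 * k3$dth + k4$dth)
      om <- om + dt / 6 * (k1$dom + 2 * k2$dom + 2 * k3$dom + k4$dom)
    }
    t_rec <- fr / rate
    rec$x[fr + 1L, ] <- x
    rec$th[fr + 1L, ] <- th
    nz_next <- noise$motor[min(fr + 1L, n_frames), ]
    rec$F[fr + 1L, ] <- ctrl_force(t_rec, x, v, nz_next)
  }
  tt <- seq(0, config$trial_duration, by = 1 / rate)
  beeps <- seq(0, config$trial_duration, by = 0.5 / config$frequency)
  trials <- lapply(seq_len(nT), function(k) {
    trial_record(time = tt,
                 force = rec$F[, k],
                 cup_pos = rec$x[, k] + noise$pos[, k],
                 ball_ang = rec$th[, k] + noise$ang[, k],
                 metronome_times = beeps,
                 subject_id = sprintf("S%02d", subject_index),
                 trial_index = k)
  })
  list(trials = trials, schedule = sched)
}

#' Generate a full synthetic cohort
#'
#' Generates `n_subjects` synthetic subjects (each with its own seed derived
#' from the cohort seed) and optionally writes the trials in the standard
#' delimited trial format together with a cohort manifest and the
#' generator's ground truth.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory; `NULL` (default) keeps the cohort in memory.
#' @param params [model_params()].
#' @return List of class `"synthetic_cohort"` with `manifest` (data frame
#'   `subject_id`, `trial_index`, `path`; paths `NA` for in-memory cohorts),
#'   `trials` (nested list, by subject), `truth` (row-bound schedules) and
#'   `config`.
#' @export
generate_cohort <- function(config, dir = NULL, params = model_params()) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- subject_seeds(config)
  manifest <- NULL
  trials <- vector("list", config$n_subjects)
  truth <- NULL
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(config$n_subjects)) {
    subj <- generate_synthetic_subject(config, i, seeds[i], params)
    trials[[i]] <- subj$trials
    sid <- sprintf("S%02d", i)
    truth <- rbind(truth, cbind(subject_id = sid, subj$schedule))
    paths <- rep(NA_character_, config$n_trials)
    if (!is.null(dir)) {
      for (k in seq_len(config$n_trials)) {
        paths[k] <- file.path(dir, sprintf("%s_trial%02d.tsv", sid, k))
        write_trial(subj$trials[[k]], paths[k])
      }
    }
    manifest <- rbind(manifest,
                      data.frame(subject_id = sid,
                                 trial_index = seq_len(config$n_trials),
                                 path = paths))
  }
  names(trials) <- sprintf("S%02d", seq_len(config$n_subjects))
  if (!is.null(dir)) {
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  structure(list(manifest = manifest, trials = trials, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d trials (seed %s)\n",
              x$config$n_subjects, x$config$n_trials, x$config$seed))
  invisible(x)
}
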