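#' Analytic cup kinematics of a strategy
#'
#' The prescribed cup motion is a peak-aligned sinusoid
#' `x(t) = (A/2) cos(2 pi f t)`: at `t = 0` the cup sits at its positive
#' peak with zero velocity, which is also where the strategy's ball states
#' `theta0`/`omega0` are defined. Velocity and acceleration are the exact
#' analytic derivatives; the cup phase is `(2 pi f t) mod 2 pi`.
#'
#' @param s A [strategy()].
#' @param time_grid Strictly increasing, uniformly spaced times (s).
#' @return A data frame with columns `time`, `cup_pos`, `cup_vel`, `cup_acc`
#'   and `phase`.
#' @examples
#' ck <- cup_kinematics(strategy(0.2, 1), seq(0, 2, by = 1 / 120))
#' max(abs(ck$cup_acc))  # (A/2) (2 pi f)^2
#' @export
cup_kinematics <- function(s, time_grid) {
  stopifnot(inherits(s, "cup_strategy"))
  check_uniform_grid(time_grid)
  a <- s$amplitude_pp / 2
  w <- 2 * pi * s$frequency
  data.frame(time = time_grid,
             cup_pos = a * cos(w * time_grid),
             cup_vel = -a * w * sin(w * time_grid),
             cup_acc = -a * w^2 * cos(w * time_grid),
             phase = (w * time_grid) %% (2 * pi))
}

check_uniform_grid <- function(time_grid, tol = 1e-9) {
  if (length(time_grid) < 2L) stop("time grid needs at least 2 points")
  dt <- diff(time_grid)
  if (any(dt <= 0)) stop("time grid must be strictly increasing")
  if (diff(range(dt)) > tol * max(dt)) {
    stop("time grid must be uniformly spaced")
  }
  invisible(mean(dt))
}

new_trajectory <- function(df, params, strategy = NULL, force_model = NA) {
  structure(df, class = c("cup_trajectory", "data.frame"),
            params = params, strategy = strategy, force_model = force_model)
}

#' @export
print.cup_trajectory <- function(x, ...) {
  dt <- diff(x$time[1:2])
  cat(sprintf("Cart-pendulum trajectory: %d samples at %.4g Hz, %.4g s\n",
              nrow(x), 1 / dt, x$time[nrow(x)] - x$time[1]))
  s <- attr(x, "strategy")
  if (!is.null(s)) print(s)
  cat(sprintf("channels: %s\n", paste(names(x), collapse = ", ")))
  invisible(x)
}

ball_rhs <- function(s, params) {
  a <- s$amplitude_pp / 2
  w <- 2 * pi * s$frequency
  l <- params$rod_length
  g <- params$gravity
  function(t, y, parms) {
    xdd <- -a * w^2 * cos(w * t)
    list(c(y[2L], (xdd * cos(y[1L]) - g * sin(y[1L])) / l))
  }
}

#' Simulate the driven ball (pendulum) under a prescribed cup sinusoid
#'
#' Integrates the ball subsystem `l theta'' = x''(t) cos(theta) - g sin(theta)`
#' with the cup acceleration of the strategy's sinusoid as the driving input.
#' The ball angle is unconstrained (full rotations allowed). Integration uses
#' an adaptive solver (deSolve's `lsoda`) at relative and absolute tolerance
#' `1e-8` by default, sampled on a uniform output grid.
#'
#' @param s A [strategy()]; `theta0`/`omega0` are the ball states at `t = 0`
#'   (a positive cup peak).
#' @param params [model_params()].
#' @param duration Simulated time in s; must cover at least one cup period.
#' @param rate Output sampling rate in Hz (default 120, the experimental
#'   recording rate).
#' @param rtol,atol Integrator tolerances.
#' @return A `"cup_trajectory"` data frame with the analytic cup channels,
#'   `ball_ang`, `ball_angvel` and `phase`; the force channel is not filled
#'   (see [inverse_dynamics_force()]).
#' @examples
#' tr <- simulate_ball(strategy(0.1, 1, theta0 = 1), model_params(), duration = 5)
#' range(tr$ball_ang)
#' @export
simulate_ball <- function(s, params = model_params(), duration = 45,
                          rate = 120, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(s, "cup_strategy"))
  if (duration < 1 / s$frequency) stop("duration must cover at least one cup period")
  tt <- seq(0, duration, by = 1 / rate)
  out <- try(deSolve::ode(y = c(s$theta0, s$omega0), times = tt,
                          func = ball_rhs(s, params), parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(tt)) {
    stop("ball integration failed: ",
         if (inherits(out, "try-error")) attr(out, "condition")$message
         else sprintf("solver stopped at t = %.3f s", out[nrow(out), 1L]))
  }
  ck <- cup_kinematics(s, tt)
  ck$ball_ang <- out[, 2L]
  ck$ball_angvel <- out[, 3L]
  ck$force <- NA_real_
  new_trajectory(ck[, c("time", "cup_pos", "cup_vel", "cup_acc",
                        "ball_ang", "ball_angvel", "force", "phase")],
                 params = params, strategy = s)
}

#' Applied hand force from the kinematics (inverse dynamics)
#'
#' Fills the force channel of a trajectory whose cup and ball channels are
#' already consistent with the ball equation of motion. Two force
#' conventions are provided:
#'
#' * `"rendered"` (default): `F = (m_cup + m_ball) x'' + m_ball a_ball`,
#'   where `a_ball` is the ball's horizontal acceleration. This is the force
#'   convention of the haptic task the package analyses, in which the hand
#'   carries the full translational inertia of the object plus the pendulum
#'   reaction; it is anchored by the period-1 fixed point of the stroboscopic
#'   map (see the package vignette).
#' * `"lagrangian"`: `F = m_cup x'' + m_ball a_ball`, the textbook
#'   cart-pendulum hand force. It differs from `"rendered"` by exactly
#'   `m_ball x''(t)` and conserves mechanical energy when `F = 0`.
#'
#' In both cases the ball's horizontal acceleration is eliminated through the
#' ball equation of motion, giving the closed forms
#' `F = x'' (m_cup + m_ball + m_ball sin^2 theta) + m_ball sin(theta) (g cos(theta) + l omega^2)`
#' (rendered) and the same with coefficient
#' `(m_cup + m_ball - m_ball cos^2 theta)` (lagrangian).
#'
#' @param trajectory A `"cup_trajectory"` with cup and ball channels.
#' @param params [model_params()].
#' @param force_model `"rendered"` or `"lagrangian"`.
#' @param check_residual Verify that the ball channels satisfy the ball
#'   equation of motion (finite-difference check) before computing the force.
#' @param residual_tol Tolerance for that check, in rad/s^2.
#' @return The trajectory with the `force` channel filled (N).
#' @examples
#' tr <- simulate_ball(strategy(0.1, 1, theta0 = 1), duration = 5)
#' tr <- inverse_dynamics_force(tr)
#' range(tr$force)
#' @export
inverse_dynamics_force <- function(trajectory, params = attr(trajectory, "params"),
                                   force_model = c("rendered", "lagrangian"),
                                   check_residual = TRUE, residual_tol = 1e-3) {
  force_model <- match.arg(force_model)
  stopifnot(inherits(trajectory, "cup_trajectory"))
  if (is.null(params)) params <- model_params()
  if (check_residual) {
    res <- ball_equation_residual(trajectory, params)
    if (max(abs(res), na.rm = TRUE) > residual_tol) {
      stop(sprintf(
        "ball channels inconsistent with the ball equation of motion (max residual %.3g rad/s^2 > %.3g)",
        max(abs(res), na.rm = TRUE), residual_tol))
    }
  }
  trajectory$force <- force_from_states(trajectory$cup_acc, trajectory$ball_ang,
                                        trajectory$ball_angvel, params, force_model)
  attr(trajectory, "force_model") <- force_model
  trajectory
}

force_from_states <- function(cup_acc, theta, omega, params, force_model) {
  m <- params$m_ball; M <- params$m_cup
  l <- params$rod_length; g <- params$gravity
  coef <- if (force_model == "rendered") M + m + m * sin(theta)^2
          else M + m - m * cos(theta)^2
  cup_acc * coef + m * sin(theta) * (g * cos(theta) + l * omega^2)
}

#' Residual of the ball equation of motion along a trajectory
#'
#' Computes `l theta'' - (x'' cos theta - g sin theta)` with `theta''`
#' obtained by fourth-order central differences of the `ball_angvel` channel
#' (second-order at the edges). The residual is finite-difference limited:
#' for smooth 120 Hz channels it is typically below 1e-4 rad/s^2.
#'
#' @param trajectory A `"cup_trajectory"`.
#' @param params [model_params()].
#' @return Numeric vector of residuals (rad/s^2), one per sample.
#' @export
ball_equation_residual <- function(trajectory, params = attr(trajectory, "params")) {
  if (is.null(params)) params <- model_params()
  dt <- check_uniform_grid(trajectory$time)
  thdd <- fd_derivative(trajectory$ball_angvel, dt)
  params$rod_length * thdd -
    (trajectory$cup_acc * cos(trajectory$ball_ang) -
       params$gravity * sin(trajectory$ball_ang))
}

#' Algebraic force-equation residual of a trajectory
#'
#' Substitutes all stored channels into the closed-form force equation of the
#' stated convention and returns `force - F(channels)`. Unlike
#' [ball_equation_residual()] this uses no finite differencing, so package
#' generated trajectories satisfy it to integrator accuracy.
#'
#' @inheritParams ball_equation_residual
#' @param force_model Which force convention the force channel uses; defaults
#'   to the trajectory's own.
#' @return Numeric vector of residuals (N).
#' @export
force_equation_residual <- function(trajectory, params = attr(trajectory, "params"),
                                    force_model = attr(trajectory, "force_model")) {
  if (is.null(params)) params <- model_params()
  if (is.null(force_model) || is.na(force_model)) force_model <- "rendered"
  trajectory$force - force_from_states(trajectory$cup_acc, trajectory$ball_ang,
                                       trajectory$ball_angvel, params, force_model)
}

# 4th-order central first derivative, one-sided 2nd-order at the edges
fd_derivative <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 5L) {
    i <- 3:(n - 2L)
    d[i] <- (-x[i + 2L] + 8 * x[i + 1L] - 8 * x[i - 1L] + x[i - 2L]) / (12 * dt)
    d[2L] <- (x[3L] - x[1L]) / (2 * dt)
    d[n - 1L] <- (x[n] - x[n - 2L]) / (2 * dt)
    d[1L] <- (-3 * x[1L] + 4 * x[2L] - x[3L]) / (2 * dt)
    d[n] <- (3 * x[n] - 4 * x[n - 1L] + x[n - 2L]) / (2 * dt)
  } else {
    d <- c(diff(x) / dt, (x[n] - x[n - 1L]) / dt)
  }
  d
}

#' Simulate a full strategy: ball dynamics plus inverse-dynamics force
#'
#' Convenience wrapper: [simulate_ball()] followed by
#' [inverse_dynamics_force()].
#'
#' @inheritParams simulate_ball
#' @inheritParams inverse_dynamics_force
#' @return A `"cup_trajectory"` with all channels filled.
#' @export
simulate_strategy <- function(s, params = model_params(), duration = 45,
                              rate = 120, force_model = "rendered",
                              rtol = 1e-8, atol = 1e-8) {
  tr <- simulate_ball(s, params, duration, rate, rtol, atol)
  inverse_dynamics_force(tr, params, force_model, check_residual = FALSE)
}

#' Forward simulation under an applied force profile
#'
#' Integrates the full four-state system (cup position/velocity, ball
#' angle/angular velocity) under a sampled applied-force profile,
#' interpolated piecewise-linearly inside the integrator. The cup
#' acceleration is recovered from the same force convention used for the
#' inverse dynamics, so an inverse-dynamics force fed back through
#' `forward_simulate` reproduces the prescribed cup trajectory.
#'
#' @param force Numeric vector of applied force samples (N) on a uniform grid.
#' @param force_rate Sampling rate of `force` in Hz.
#' @param params [model_params()].
#' @param initial_state Numeric length-4: cup position (m), cup velocity
#'   (m/s), ball angle (rad), ball angular velocity (rad/s) at `t = 0`.
#' @param duration Simulated time (s); defaults to the force profile's span.
#' @param rate Output rate (Hz).
#' @param force_model `"rendered"` or `"lagrangian"` (see
#'   [inverse_dynamics_force()]). With `"lagrangian"` and `F = 0` the system
#'   conserves mechanical energy and oscillates freely in its anti-phase mode.
#' @param rtol,atol Integrator tolerances.
#' @return A `"cup_trajectory"`; the `phase` channel is `NA` (no prescribed
#'   sinusoid exists for a forward run).
#' @examples
#' tr <- simulate_strategy(strategy(0.1, 1, theta0 = 1), duration = 5)
#' rt <- forward_simulate(tr$force, 120, initial_state = c(0.05, 0, 1, 0),
#'                        duration = 5)
#' max(abs(rt$cup_pos - tr$cup_pos))
#' @export
forward_simulate <- function(force, force_rate, params = model_params(),
                             initial_state = c(0, 0, 0, 0),
                             duration = (length(force) - 1) / force_rate,
                             rate = 120,
                             force_model = c("rendered", "lagrangian"),
                             rtol = 1e-8, atol = 1e-8) {
  force_model <- match.arg(force_model)
  stopifnot(length(initial_state) == 4L, all(is.finite(initial_state)))
  f_time <- (seq_along(force) - 1L) / force_rate
  f_fun <- stats::approxfun(f_time, force, rule = 2)
  m <- params$m_ball; M <- params$m_cup
  l <- params$rod_length; g <- params$gravity
  rhs <- function(t, y, parms) {
    th <- y[3L]; om <- y[4L]
    coef <- if (force_model == "rendered") M + m + m * sin(th)^2
            else M + m - m * cos(th)^2
    xdd <- (f_fun(t) - m * sin(th) * (g * cos(th) + l * om^2)) / coef
    list(c(y[2L], xdd, om, (xdd * cos(th) - g * sin(th)) / l))
  }
  tt <- seq(0, duration, by = 1 / rate)
  out <- try(deSolve::ode(y = initial_state, times = tt, func = rhs,
                          parms = NULL, method = "lsoda",
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(tt)) {
    stop("forward integration failed: ",
         if (inherits(out, "try-error")) attr(out, "condition")$message
         else sprintf("solver stopped at t = %.3f s", out[nrow(out), 1L]))
  }
  th <- out[, 4L]; om <- out[, 5L]
  Fv <- f_fun(tt)
  coef <- if (force_model == "rendered") M + m + m * sin(th)^2
          else M + m - m * cos(th)^2
  xdd <- (Fv - m * sin(th) * (g * cos(th) + l * om^2)) / coef
  df <- data.frame(time = tt, cup_pos = out[, 2L], cup_vel = out[, 3L],
                   cup_acc = xdd, ball_ang = th, ball_angvel = om,
                   force = Fv, phase = NA_real_)
  new_trajectory(df, params = params, force_model = force_model)
}

#' Locate a period-1 fixed point of the stroboscopic map
#'
#' Newton refinement of the ball state `(theta0, omega0)` such that the
#' driven ball returns exactly to it after one cup period: the period-1
#' orbit whose strobed force is a single repeated value. Starting near the
#' anti-phase solution (`theta0 = 1`, `omega0 = 0`) converges to the fixed
#' point underlying the constant-strobe branch of the bifurcation diagram.
#'
#' @param amplitude_pp Peak-to-peak cup amplitude (m).
#' @param frequency Cup frequency (Hz).
#' @param params [model_params()].
#' @param theta0,omega0 Initial guess for the ball state at the cup peak.
#' @param tol Convergence tolerance on the return-map residual.
#' @param max_iter Maximum Newton iterations.
#' @return A [strategy()] at the fixed point, with attribute `"residual"`
#'   (the final return-map mismatch).
#' @export
find_period1_strategy <- function(amplitude_pp, frequency = 1,
                                  params = model_params(),
                                  theta0 = 1, omega0 = 0,
                                  tol = 1e-10, max_iter = 25) {
  period_map <- function(v) {
    s <- strategy(amplitude_pp, frequency, theta0 = v[1L], omega0 = v[2L])
    out <- deSolve::ode(y = v, times = c(0, 1 / frequency),
                        func = ball_rhs(s, params), parms = NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-11)
    out[2L, 2:3]
  }
  v <- c(theta0, omega0)
  for (it in seq_len(max_iter)) {
    r <- period_map(v) - v
    if (sqrt(sum(r^2)) < tol) break
    eps <- 1e-7
    J <- matrix(0, 2, 2)
    for (k in 1:2) {
      dv <- v; dv[k] <- dv[k] + eps
      J[, k] <- ((period_map(dv) - dv) - r) / eps
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    v <- v - step
  }
  res <- sqrt(sum((period_map(v) - v)^2))
  if (res > 1e-6) {
    warning(sprintf("fixed-point refinement did not converge (residual %.3g)", res))
  }
  structure(strategy(amplitude_pp, frequency, theta0 = v[1L], omega0 = v[2L]),
            residual = res)
}

#' Mechanical energy of the conservative cart-pendulum
#'
#' Total kinetic plus potential energy of the textbook (Lagrangian)
#' cart-pendulum, `E = (m_cup + m_ball) v^2 / 2 - m_ball l v omega cos(theta)
#' + m_ball l^2 omega^2 / 2 - m_ball g l cos(theta)`. Conserved along
#' force-free trajectories of the `"lagrangian"` forward model (the
#' `"rendered"` convention is not conservative).
#'
#' @param trajectory A `"cup_trajectory"`.
#' @param params [model_params()].
#' @return Numeric vector of energies (J), one per sample.
#' @export
mechanical_energy <- function(trajectory, params = attr(trajectory, "params")) {
  if (is.null(params)) params <- model_params()
  m <- params$m_ball; M <- params$m_cup
  l <- params$rod_length; g <- params$gravity
  v <- trajectory$cup_vel; om <- trajectory$ball_angvel
  th <- trajectory$ball_ang
  0.5 * (M + m) * v^2 - m * l * v * om * cos(th) +
    0.5 * m * l^2 * om^2 - m * g * l * cos(th)
}

#' Linear vibration-mode analysis of the free object
#'
#' Linearises the force-free cart-pendulum about the hanging equilibrium.
#' The system has a zero-frequency free-motion mode (rigid translation) and
#' one oscillatory anti-phase mode with natural frequency
#' `f = sqrt((g / l) (1 + m_ball / m_cup)) / (2 pi)`.
#' Because the centre of mass is stationary in free oscillation and the
#' ball's horizontal excursion is bounded by the rod length, the largest
#' force-free peak-to-peak cup amplitude is
#' `2 l m_ball / (m_ball + m_cup)`.
#'
#' @param params [model_params()].
#' @return A list with `mode_frequencies` (Hz; zero mode first),
#'   `antiphase_mode_shape` (cup displacement per unit ball angle, m/rad,
#'   with the ball-angle component normalised to 1) and
#'   `max_free_cup_amplitude_pp` (m).
#' @examples
#' linear_mode_analysis(model_params())
#' @export
linear_mode_analysis <- function(params = model_params()) {
  m <- params$m_ball; M <- params$m_cup
  l <- params$rod_length; g <- params$gravity
  f_anti <- sqrt((g / l) * (1 + m / M)) / (2 * pi)
  list(mode_frequencies = c(0, f_anti),
       antiphase_mode_shape = c(cup = m * l / (M + m), ball_angle = 1),
       max_free_cup_amplitude_pp = 2 * l * m / (m + M))
}
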