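#' Finite-time (global) Lyapunov exponent of the driven ball subsystem
#'
#' Largest finite-time Lyapunov exponent of the two-state ball subsystem
#' driven by the strategy's sinusoidal cup acceleration. The reference ball
#' trajectory is integrated adaptively (tolerance 1e-8), then a tangent
#' vector is propagated through the variational (linearised) dynamics with
#' Jacobian
#' `J(t) = [[0, 1], [(-x''(t) sin(theta) - g cos(theta)) / l, 0]]`
#' in renormalised steps of `step` seconds: after each step the log of the
#' growth factor is accumulated and the vector rescaled to unit length. The
#' exponent is the accumulated log growth divided by the horizon,
#' `lambda = (1/T) sum ln |J_step u| / |u|`, computed separately from initial
#' unit vectors along the angle and the angular-velocity directions; the
#' larger of the two is returned (both are attached as an attribute).
#'
#' A positive exponent rules out a stable limit cycle for that strategy; for
#' the undriven (zero-amplitude) pendulum the exponent tends to zero as the
#' horizon grows (neutral stability of a conservative oscillator).
#'
#' @param s A [strategy()].
#' @param params [model_params()].
#' @param duration Horizon T in s (default 60; at least 10).
#' @param step Renormalisation step (s), default 0.01.
#' @param rtol,atol Tolerances for the reference-trajectory integration.
#' @return Scalar exponent (1/s) with attribute `"per_direction"` holding
#'   both directional estimates.
#' @examples
#' global_lyapunov(strategy(0.1, 1, theta0 = -1.35), duration = 20)
#' @export
global_lyapunov <- function(s, params = model_params(), duration = 60,
                            step = 0.01, rtol = 1e-8, atol = 1e-8) {
  if (duration < 10) stop("duration below 10 s gives an unreliable estimate")
  n_steps <- floor(duration / step)
  duration <- n_steps * step
  # reference trajectory sampled at half the renormalisation step so the
  # tangent propagation has midpoint states for its Runge-Kutta stages
  tt <- seq(0, duration, by = step / 2)
  out <- try(deSolve::ode(y = c(s$theta0, s$omega0), times = tt,
                          func = ball_rhs(s, params), parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(tt)) {
    stop("reference trajectory integration failed")
  }
  th <- out[, 2L]
  a <- s$amplitude_pp / 2
  w <- 2 * pi * s$frequency
  l <- params$rod_length; g <- params$gravity
  xdd <- -a * w^2 * cos(w * tt)
  jlow <- (-xdd * sin(th) - g * cos(th)) / l   # d(theta'')/d(theta) at samples
  lam <- vapply(list(c(1, 0), c(0, 1)), function(u0) {
    u <- u0
    acc <- 0
    h <- step
    for (k in seq_len(n_steps)) {
      i0 <- 2L * k - 1L                 # sample at t, t + h/2, t + h
      a0 <- jlow[i0]; a1 <- jlow[i0 + 1L]; a2 <- jlow[i0 + 2L]
      # classical RK4 for u' = J(t) u with J evaluated at the three nodes
      k1 <- c(u[2L], a0 * u[1L])
      y2 <- u + h / 2 * k1
      k2 <- c(y2[2L], a1 * y2[1L])
      y3 <- u + h / 2 * k2
      k3 <- c(y3[2L], a1 * y3[1L])
      y4 <- u + h * k3
      k4 <- c(y4[2L], a2 * y4[1L])
      u <- u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      nrm <- sqrt(sum(u^2))
      acc <- acc + log(nrm)
      u <- u / nrm
    }
    acc / duration
  }, numeric(1))
  structure(max(lam), per_direction = c(theta = lam[1L], omega = lam[2L]))
}
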