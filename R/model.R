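#' Physical parameters of the cart-pendulum (cup-and-ball) object
#'
#' Container for the physical constants of the manipulated object: a cup of
#' mass `m_cup` sliding along a horizontal line, with a ball of mass `m_ball`
#' rolling along the cup's circular arc of radius `rod_length`, mechanically
#' equivalent to a point-mass pendulum suspended from the cup.
#'
#' @param m_ball Ball (pendulum bob) mass in kg.
#' @param m_cup Cup (cart) mass in kg.
#' @param rod_length Pendulum rod length in m (radius of the cup's arc).
#' @param gravity Gravitational acceleration in m/s^2.
#'
#' @return An object of class `"model_params"`, a named list with the four
#'   constants. All must be strictly positive.
#'
#' @details The defaults (0.6 kg, 2.4 kg, 0.25 m, 9.81 m/s^2) are the task
#'   parameterisation used throughout the package's worked examples.
#'
#' @examples
#' p <- model_params()
#' linear_mode_analysis(p)
#' @export
model_params <- function(m_ball = 0.6, m_cup = 2.4, rod_length = 0.25,
                         gravity = 9.81) {
  vals <- c(m_ball = m_ball, m_cup = m_cup, rod_length = rod_length,
            gravity = gravity)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all model parameters must be finite and strictly positive")
  }
  structure(list(m_ball = m_ball, m_cup = m_cup, rod_length = rod_length,
                 gravity = gravity),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Cart-pendulum model parameters\n")
  cat(sprintf("  ball mass   : %.3g kg\n", x$m_ball))
  cat(sprintf("  cup mass    : %.3g kg\n", x$m_cup))
  cat(sprintf("  rod length  : %.3g m\n", x$rod_length))
  cat(sprintf("  gravity     : %.3g m/s^2\n", x$gravity))
  invisible(x)
}

#' Define a rhythmic manipulation strategy (execution variables)
#'
#' A strategy is one point of the task's result space: the four scalar
#' execution variables that fully determine the object's motion when the cup
#' follows a pure sinusoid. The cup trajectory is peak-aligned,
#' `x(t) = (A/2) cos(2 pi f t)`, so `t = 0` is a positive cup-position peak
#' and `theta0`, `omega0` are the ball states at that peak.
#'
#' @param amplitude_pp Full peak-to-peak cup displacement in m (>= 0).
#' @param frequency Cup oscillation frequency in Hz (> 0).
#' @param theta0 Ball angle at the cup-position peak, rad. Positive angles
#'   displace the ball opposite to positive cup displacement, so anti-phase
#'   coordination has `theta0 > 0`.
#' @param omega0 Ball angular velocity at the cup-position peak, rad/s.
#'
#' @return An object of class `"cup_strategy"`.
#' @seealso [strategy_in_domain()] for the standard map-domain check.
#' @examples
#' s <- strategy(amplitude_pp = 0.10, frequency = 1, theta0 = 1.0)
#' strategy_in_domain(s)
#' @export
strategy <- function(amplitude_pp, frequency = 1, theta0 = 0, omega0 = 0) {
  vals <- c(amplitude_pp, frequency, theta0, omega0)
  if (length(vals) != 4L || !all(is.finite(vals))) {
    stop("strategy requires four finite scalars")
  }
  if (frequency <= 0) stop("frequency must be > 0")
  if (amplitude_pp < 0) stop("amplitude_pp must be >= 0")
  structure(list(amplitude_pp = amplitude_pp, frequency = frequency,
                 theta0 = theta0, omega0 = omega0),
            class = "cup_strategy")
}

#' @export
print.cup_strategy <- function(x, ...) {
  cat(sprintf(
    "Strategy: A = %.3g m pp, f = %.3g Hz, theta0 = %.3g rad, omega0 = %.3g rad/s\n",
    x$amplitude_pp, x$frequency, x$theta0, x$omega0))
  if (!strategy_in_domain(x)) cat("  (outside the standard map domain)\n")
  invisible(x)
}

#' Standard execution-variable ranges of the result-space maps
#'
#' @return Named list of two-element ranges for `frequency` (Hz),
#'   `amplitude_pp` (m), `theta0` (rad) and `omega0` (rad/s).
#' @export
map_domain <- function() {
  list(frequency = c(0.8, 1.2),
       amplitude_pp = c(0.08, 0.44),
       theta0 = c(-pi / 2, pi / 2),
       omega0 = c(-3, 3))
}

#' Is a strategy inside the standard map domain?
#'
#' Checks the four execution variables against the ranges used for the
#' result-space maps (frequency 0.8-1.2 Hz, amplitude 8-44 cm peak-to-peak,
#' ball angle within +/- pi/2 rad, ball angular velocity within +/- 3 rad/s).
#'
#' @param s A [strategy()].
#' @param domain Ranges as returned by [map_domain()].
#' @return Logical scalar; attribute `"violations"` names out-of-range fields
#'   when `FALSE`.
#' @export
strategy_in_domain <- function(s, domain = map_domain()) {
  stopifnot(inherits(s, "cup_strategy"))
  bad <- character(0)
  for (field in names(domain)) {
    r <- domain[[field]]
    v <- s[[field]]
    if (v < r[1] || v > r[2]) bad <- c(bad, field)
  }
  structure(length(bad) == 0L, violations = bad)
}
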