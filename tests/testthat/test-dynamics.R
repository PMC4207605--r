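test_that("cup kinematics are the peak-aligned sinusoid with exact derivatives", {
  tt <- seq(0, 5, by = 1 / 120)
  ck0 <- cup_kinematics(strategy(0, 1), tt)
  expect_true(all(ck0$cup_pos == 0) && all(ck0$cup_acc == 0))

  ck <- cup_kinematics(strategy(0.2, 1), tt)
  expect_equal(max(abs(ck$cup_pos)), 0.1)
  expect_equal(max(abs(ck$cup_acc)), 0.1 * (2 * pi)^2, tolerance = 1e-6)
  expect_equal(ck$cup_pos[1], 0.1)       # t = 0 sits on the positive peak
  expect_equal(ck$cup_vel[1], 0)
  expect_true(all(ck$phase >= 0 & ck$phase < 2 * pi))

  expect_error(cup_kinematics(strategy(0.2, 1), c(0, 0.1, 0.3)), "uniform")
  expect_error(cup_kinematics(strategy(0.2, 1), c(0, -0.1, -0.2)), "increasing")
})

test_that("ball simulation reproduces equilibrium and small-angle closed forms", {
  eq <- simulate_ball(strategy(0, 1, theta0 = 0, omega0 = 0), duration = 5)
  expect_lt(max(abs(eq$ball_ang)), 1e-10)

  sm <- simulate_ball(strategy(0, 1, theta0 = 0.05), duration = 30)
  pk <- detect_cycle_peaks(sm$ball_ang, 120, nominal_f = 1)
  f_est <- 1 / mean(diff(pk$maxima$time))
  expect_equal(f_est, sqrt(9.81 / 0.25) / (2 * pi), tolerance = 1e-3)
})

test_that("the period-1 anchor pins the time-origin convention", {
  # the stroboscopic fixed point sits at the anti-phase anchor angle
  sfp <- p1_fixed_point()
  expect_lt(abs(sfp$theta0 - 1), 0.01)
  expect_lt(abs(sfp$omega0), 1e-6)
  # starting exactly at (1, 0) stays on a near-period-1 orbit: the ball state
  # returns to (1, 0) at every cup peak
  st <- strobe_at_cup_peaks(p1_trajectory())
  expect_lt(max(abs(st$ball_ang_at_peak - 1)), 0.01)
  expect_lt(max(abs(st$ball_angvel_at_peak)), 0.05)
})

test_that("inverse dynamics matches closed forms and rejects bad ball channels", {
  # static system: no cup motion, hanging ball, no force
  tt <- seq(0, 5, by = 1 / 120)
  static <- simulate_strategy(strategy(0, 1, theta0 = 0), duration = 5)
  expect_lt(max(abs(static$force)), 1e-9)

  # stationary cup, small swing: F ~ m g theta
  sw <- simulate_strategy(strategy(0, 1, theta0 = 0.1), duration = 10)
  expect_equal(max(abs(sw$force)), 0.6 * 9.81 * sin(0.1) * cos(0.1),
               tolerance = 1e-3)

  bad <- simulate_ball(p1_strategy(), duration = 5)
  bad$ball_ang <- bad$ball_ang + 0.05 * sin(20 * bad$time)
  expect_error(inverse_dynamics_force(bad), "residual")
})

test_that("forward simulation inverts the inverse dynamics", {
  tr <- p1_trajectory()
  rt <- forward_simulate(tr$force, 120,
                         initial_state = c(0.05, 0, 1, 0), duration = 45)
  expect_lt(max(abs(rt$cup_pos - tr$cup_pos)), 1e-4)
  expect_lt(max(abs(rt$ball_ang - tr$ball_ang)), 1e-3)

  z <- forward_simulate(rep(0, 601), 120, initial_state = c(0, 0, 0, 0))
  expect_true(all(abs(as.matrix(z[, 2:7])) < 1e-12))
})

test_that("the unforced conservative model oscillates at its anti-phase mode", {
  p <- model_params()
  th0 <- 0.1
  x0 <- -p$m_ball * p$rod_length / (p$m_ball + p$m_cup) * th0
  fr <- forward_simulate(rep(0, 45 * 120 + 1), 120,
                         initial_state = c(x0, 0, th0, 0), duration = 45,
                         force_model = "lagrangian")
  pk <- detect_cycle_peaks(fr$ball_ang, 120, nominal_f = 1.1)
  expect_equal(1 / mean(diff(pk$maxima$time)), 1.11, tolerance = 5e-3)
  # energy bookkeeping: total mechanical energy constant to solver accuracy
  expect_lt(diff(range(mechanical_energy(fr))), 1e-6)
})

test_that("linear mode analysis gives the closed-form modes and amplitude bound", {
  lm <- linear_mode_analysis(model_params())
  expect_equal(lm$mode_frequencies[1], 0)
  expect_equal(lm$mode_frequencies[2],
               sqrt((9.81 / 0.25) * (1 + 0.6 / 2.4)) / (2 * pi))
  expect_equal(lm$max_free_cup_amplitude_pp, 0.1)
  # vanishing ball mass: the mode tends to the bare pendulum frequency
  lm0 <- linear_mode_analysis(model_params(m_ball = 1e-9))
  expect_equal(lm0$mode_frequencies[2], sqrt(9.81 / 0.25) / (2 * pi),
               tolerance = 1e-6)
})

test_that("returned trajectories satisfy the equations of motion", {
  for (tr in list(p1_trajectory(), chaotic_trajectory())) {
    expect_lt(max(abs(force_equation_residual(tr))), 1e-6)
    res <- ball_equation_residual(tr)
    expect_lt(stats::median(abs(res)), 1e-3)  # finite-difference limited
  }
})
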