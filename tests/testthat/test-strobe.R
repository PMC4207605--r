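test_that("strobing samples every positive cup peak including the boundaries", {
  st <- strobe_at_cup_peaks(p1_trajectory())
  expect_length(st$peak_times, 46)           # t = 0, 1, ..., 45
  expect_equal(st$peak_times, 0:45, tolerance = 1e-9)
  expect_lt(stats::var(st$force_at_peak), 1e-3)   # period-1: constant strobe
  expect_equal(st$cycle_amplitude_pp, rep(0.1, 45))
  expect_length(st$cycle_period, 45)
})

test_that("numeric peak strobing agrees with the analytic peak times", {
  tr <- qp_trajectory()
  attr(tr, "strategy") <- NULL               # force numeric detection
  st_num <- strobe_at_cup_peaks(tr, nominal_f = 1)
  st_ana <- strobe_at_cup_peaks(qp_trajectory())
  expect_equal(length(st_num$peak_times), length(st_ana$peak_times))
  expect_lt(max(abs(st_num$peak_times - st_ana$peak_times)), 1e-3)
  expect_lt(max(abs(st_num$force_at_peak - st_ana$force_at_peak)), 0.05)
})

test_that("strobing a constant cup position fails", {
  tt <- seq(0, 10, by = 1 / 120)
  flat <- data.frame(time = tt, cup_pos = 1, cup_vel = 0, cup_acc = 0,
                     ball_ang = 0, ball_angvel = 0, force = 0, phase = 0)
  class(flat) <- c("cup_trajectory", "data.frame")
  expect_error(strobe_at_cup_peaks(flat), "constant|extrema|peaks")
})

test_that("bifurcation scan separates periodic, quasi-periodic and chaotic regimes", {
  sc <- suppressWarnings(
    bifurcation_scan(c(1.0, 0.4, NaN), duration = 45))
  summ <- sc$summary
  expect_lt(summ$var[1], 1e-3)                      # theta0 = 1.0: period-1
  expect_equal(summ$min[2], -6.59, tolerance = 0.05)
  expect_equal(summ$max[2], -1.37, tolerance = 0.05)
  # a failed grid point is logged, not fatal
  expect_true(is.na(summ$min[3]))
  expect_equal(summ$n[3], 0L)
  long <- as.data.frame(sc)
  expect_named(long, c("theta0_rad", "strobe_index", "force_N"))
  expect_equal(nrow(long), sum(summ$n))
})
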