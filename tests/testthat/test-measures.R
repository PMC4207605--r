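test_that("mutual information is non-negative, affine invariant and null-calibrated", {
  tr <- p1_trajectory()
  mi <- mutual_information(tr$force, tr$phase)
  expect_gt(mi, 0)
  # affine rescaling of the force leaves MI unchanged
  expect_equal(mutual_information(2 * tr$force + 5, tr$phase), mi,
               tolerance = 1e-2)
  # independent surrogates carry (almost) no information
  set.seed(11)
  shuffled <- mutual_information(sample(tr$force), tr$phase)
  expect_lt(shuffled, 0.01)
  # non-negativity on arbitrary series
  set.seed(12)
  for (k in 1:5) {
    f <- stats::rnorm(800)
    ph <- stats::runif(800, 0, 2 * pi)
    expect_gte(mutual_information(f, ph), 0)
  }
  expect_warning(mi0 <- mutual_information(rep(1, 100),
                                           stats::runif(100, 0, 2 * pi)),
                 "constant")
  expect_equal(mi0, 0)
})

test_that("structured force-phase coupling exceeds the shuffle distribution", {
  tr <- simulate_strategy(strategy(0.1, 1, theta0 = 1), duration = 12)
  mi <- mutual_information(tr$force, tr$phase)
  set.seed(21)
  null <- replicate(100, mutual_information(sample(tr$force), tr$phase))
  expect_gt(mi, stats::quantile(null, 0.95))
  # and one more independent surrogate falls below that same bound
  set.seed(22)
  expect_lt(mutual_information(sample(tr$force), tr$phase),
            stats::quantile(null, 0.95) * 2)
  # period-1 coupling is tighter than chaotic coupling at the same amplitude
  expect_gt(mutual_information(p1_trajectory()$force, p1_trajectory()$phase),
            mutual_information(chaotic_trajectory()$force,
                               chaotic_trajectory()$phase))
})

test_that("the MI kernel density agrees with an independent 2D KDE", {
  skip_if_not_installed("MASS")
  # data confined away from the phase boundary, so circular replication is
  # inactive and the estimate must equal a plain product-Gaussian KDE
  set.seed(5)
  ph <- stats::runif(2000, 1.5, 4.5)
  f <- sin(ph) + stats::rnorm(2000, 0, 0.3)
  hF <- 0.2; hP <- 0.25
  mi_pkg <- mutual_information(f, ph, bw = c(hF, hP))
  n_grid <- 128
  Fg <- seq(min(f) - 3 * hF, max(f) + 3 * hF, length.out = n_grid)
  Pg <- seq(0, 2 * pi, length.out = n_grid + 1)[1:n_grid]
  kd <- MASS::kde2d(f, ph, h = 4 * c(hF, hP), n = n_grid,
                    lims = c(range(Fg), Pg[1], Pg[n_grid]))
  p <- kd$z
  wF <- rep(diff(Fg)[1], n_grid); wF[c(1, n_grid)] <- wF[1] / 2
  wP <- rep(2 * pi / n_grid, n_grid)
  p <- p / as.numeric(t(wF) %*% p %*% wP)
  pF <- as.numeric(p %*% wP)
  pP <- as.numeric(t(wF) %*% p)
  W <- outer(wF, wP); ref <- outer(pF, pP)
  pos <- p > .Machine$double.eps & ref > 0
  mi_oracle <- sum(W[pos] * p[pos] * log(p[pos] / ref[pos]))
  expect_equal(mi_pkg, mi_oracle, tolerance = 1e-10)
})

test_that("predictability index follows its defining identities", {
  expect_equal(predictability_index(rep(2.5, 10), 1), 1)
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(predictability_index(x, stats::var(x)), 0)
  expect_error(predictability_index(x, 0), "positive")
  expect_error(predictability_index(x[1:3], 1), "5")
  st <- strobe_at_cup_peaks(p1_trajectory())
  expect_equal(predictability_index(st, 1), 1, tolerance = 1e-3)
})

test_that("mean squared force matches closed forms and scales quadratically", {
  expect_equal(mean_squared_force(rep(-3, 50)), 9)
  tt <- seq(0, 1, by = 1 / 120)[-121]          # integer cycles
  expect_equal(mean_squared_force(4 * sin(2 * pi * tt)), 8)
  f <- stats::rnorm(500)
  expect_equal(mean_squared_force(3 * f), 9 * mean_squared_force(f))
  expect_error(mean_squared_force(numeric(0)), "empty")
})

test_that("normalized mean absolute jerk of a pure sinusoid is 2/pi", {
  for (case in list(c(a = 1, f = 1, rate = 120, dur = 30),
                    c(a = 0.37, f = 2.5, rate = 240, dur = 20),
                    c(a = 12, f = 0.7, rate = 120, dur = 40))) {
    tt <- seq(0, case[["dur"]], by = 1 / case[["rate"]])
    s <- case[["a"]] * sin(2 * pi * case[["f"]] * tt + 0.2)
    expect_equal(mean_abs_jerk(s, case[["rate"]]), 2 / pi, tolerance = 1e-3)
    expect_equal(mean_abs_jerk(s, case[["rate"]],
                               normalization = "cycle_amplitude",
                               cycle_frequency = case[["f"]]),
                 2 / pi, tolerance = 2e-3)
  }
})

test_that("jerk handles degenerate input and scales as expected", {
  expect_equal(mean_abs_jerk(rep(1, 100), 120), 0)
  expect_error(mean_abs_jerk(1:4, 120), "5 samples")
  tt <- seq(0, 10, by = 1 / 120)
  s <- sin(2 * pi * tt)
  raw1 <- mean_abs_jerk(s, 120, normalized = FALSE)
  expect_equal(mean_abs_jerk(5 * s, 120, normalized = FALSE), 5 * raw1)
  expect_equal(mean_abs_jerk(5 * s, 120), mean_abs_jerk(s, 120))  # invariant
})

test_that("spectral arc length ranks smoothness and is scale invariant", {
  tt <- seq(0, 10, by = 1 / 120)
  s1 <- sin(2 * pi * tt)
  s2 <- sin(2 * pi * tt) + 0.6 * sin(6 * pi * tt)
  expect_lte(spectral_arc_length(s1, 120), 0)
  expect_gt(spectral_arc_length(s1, 120), spectral_arc_length(s2, 120))
  expect_equal(spectral_arc_length(10 * s1, 120), spectral_arc_length(s1, 120))
  set.seed(31)
  noise <- stats::rnorm(length(tt))
  sal <- sapply(c(0, 0.6, 2), function(sd) {
    spectral_arc_length(s1 + sd * noise, 120)
  })
  expect_true(all(diff(sal) < 0))   # noisier = less smooth = more negative
  expect_error(spectral_arc_length(rep(0, 1200), 120), "zero")
  expect_error(spectral_arc_length(s1[1:10], 120), "samples")
})

test_that("strategy_measures bundles a consistent measure set", {
  ms <- strategy_measures(strategy(0.1, 1, theta0 = 1), duration = 20,
                          gle_duration = 20)
  expect_s3_class(ms, "measure_set")
  expect_gt(ms$mi, 0)
  expect_gt(ms$predictability_index, 0.99)  # period-1: repeatable strobes
  expect_gt(ms$gle, 0)
  expect_lt(ms$strobe_var, 1e-3)
  expect_lte(ms$sal, 0)
  expect_true(all(unlist(ms[c("msf", "jerk_ball_norm", "jerk_ball_raw",
                              "jerk_force_raw", "jerk_cup_raw")]) >= 0))
})
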