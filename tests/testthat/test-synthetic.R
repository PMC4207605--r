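small_config <- function(...) {
  cohort_config(n_subjects = 2, n_trials = 4, seed = 99, ...)
}

test_that("clean trials have the promised shape and satisfy the dynamics", {
  tr <- clean_p1_trial()
  expect_length(tr$time, 45 * 120 + 1)        # endpoint inclusive
  expect_equal(tr$metronome_times, seq(0, 45, by = 0.5))
  # channels satisfy the force equation to integrator accuracy
  traj <- simulate_strategy(p1_fixed_point(), duration = 45)
  expect_lt(max(abs(force_equation_residual(traj))), 1e-6)
  # period-1 fixed point: repeatable strobes
  st <- strobe_at_cup_peaks(traj)
  expect_lt(stats::var(st$force_at_peak), 1e-6)
})

test_that("cohort configuration validates its fields", {
  expect_error(cohort_config(chaotic_episode_prob_early = 1.5), "\\[0, 1\\]")
  expect_error(cohort_config(motor_noise_sd = -1), "motor_noise_sd")
  expect_error(cohort_config(n_subjects = 0), "empty")
  expect_error(cohort_config(amplitude_start = -0.1), "positive")
})

test_that("the generator is bit-reproducible for a fixed seed", {
  cfg <- small_config()
  a <- generate_synthetic_subject(cfg, 1)
  b <- generate_synthetic_subject(cfg, 1)
  expect_identical(a$schedule, b$schedule)
  expect_identical(a$trials[[3]]$cup_pos, b$trials[[3]]$cup_pos)
  expect_identical(a$trials[[3]]$force, b$trials[[3]]$force)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); x1 <- stats::rnorm(1)
  set.seed(1); invisible(generate_synthetic_subject(cfg, 1)); x2 <- stats::rnorm(1)
  expect_identical(x1, x2)
})

test_that("amplitude schedules carry the programmed learning curve", {
  cfg <- cohort_config(seed = 3)
  slopes <- vapply(1:100, function(k) {
    sched <- strategy_schedule(cfg, k)
    unname(stats::coef(stats::lm(amplitude_target ~ trial, sched))[2])
  }, numeric(1))
  expect_gte(mean(slopes > 0), 0.95)
  # zero-learning schedules have no systematic trend
  cfg0 <- cohort_config(amplitude_start = 0.25, amplitude_end = 0.25, seed = 3)
  slopes0 <- vapply(1:100, function(k) {
    sched <- strategy_schedule(cfg0, k)
    unname(stats::coef(stats::lm(amplitude_target ~ trial, sched))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes0 > 0) - 0.5), 0.15)
})

test_that("simulated subjects track their targets into the anti-phase half-plane", {
  cfg <- cohort_config(n_subjects = 1, n_trials = 3, seed = 17,
                       chaotic_episode_prob_early = 0)
  subj <- generate_synthetic_subject(cfg, 1)
  ev <- estimate_execution_variables(subj$trials[[3]])
  expect_equal(unname(ev$means["frequency"]), 1, tolerance = 0.03)
  expect_equal(unname(ev$means["amplitude_pp"]),
               subj$schedule$amplitude_target[3], tolerance = 0.1)
  expect_gt(unname(ev$means["theta0"]), 0)     # anti-phase coordination
})

test_that("cohort generation writes trials, manifest and ground truth", {
  dir <- tempfile("cohort")
  cfg <- small_config()
  coh <- generate_cohort(cfg, dir = dir)
  expect_equal(nrow(coh$manifest), 8)
  expect_length(list.files(dir, pattern = "^S\\d+_trial\\d+\\.tsv$"), 8)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  back <- read_cohort(file.path(dir, "manifest.tsv"))
  expect_equal(back$trials$S02[[3]]$cup_pos, coh$trials$S02[[3]]$cup_pos,
               tolerance = 1e-6)
  expect_equal(back$trials$S01[[1]]$metronome_times,
               coh$trials$S01[[1]]$metronome_times)
})
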