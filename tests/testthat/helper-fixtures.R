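# memoised fixtures shared across test files; everything is generated in
# code so the suite needs no stored data
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, fun(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# Fig-3-style period-1 strategy (10 cm pp, 1 Hz, anti-phase) and friends
p1_strategy <- function() strategy(0.1, 1, theta0 = 1, omega0 = 0)

p1_fixed_point <- function() {
  fixture("p1_fixed_point", function() find_period1_strategy(0.1, 1))
}

p1_trajectory <- function() {
  fixture("p1_traj", function() simulate_strategy(p1_strategy(), duration = 45))
}

qp_trajectory <- function() {  # quasi-periodic branch of the bifurcation scan
  fixture("qp_traj", function() {
    simulate_strategy(strategy(0.1, 1, theta0 = 0.4), duration = 45)
  })
}

chaotic_trajectory <- function() {
  fixture("chaos_traj", function() {
    simulate_strategy(strategy(0.1, 1, theta0 = -1.35), duration = 45)
  })
}

clean_p1_trial <- function() {
  fixture("clean_p1_trial", function() generate_clean_trial(p1_fixed_point()))
}

# small trial record with analytic channels, for constructed-case tests
cosine_trial <- function(force = NULL, duration = 45, rate = 120,
                         amplitude_pp = 0.2, beep_shift = 0) {
  tt <- seq(0, duration, by = 1 / rate)
  if (is.null(force)) force <- sin(2 * pi * tt)
  trial_record(time = tt, force = force,
               cup_pos = amplitude_pp / 2 * cos(2 * pi * tt),
               ball_ang = 0.5 * sin(2 * pi * tt + 0.4),
               metronome_times = seq(0, duration, by = 0.5) + beep_shift,
               subject_id = "T", trial_index = 1L)
}
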