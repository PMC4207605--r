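#' Write / read a trajectory as a delimited text table
#'
#' The on-disk format is a tab-separated table with the canonical header
#' `time_s, force_N, cup_pos_m, cup_vel_mps, cup_acc_mps2, ball_ang_rad,
#' ball_angvel_radps, phase_rad`.
#'
#' @param trajectory A `"cup_trajectory"`.
#' @param path Output file.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `"cup_trajectory"` (without params/strategy provenance).
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cup_trajectory"))
  df <- data.frame(time_s = trajectory$time,
                   force_N = trajectory$force,
                   cup_pos_m = trajectory$cup_pos,
                   cup_vel_mps = trajectory$cup_vel,
                   cup_acc_mps2 = trajectory$cup_acc,
                   ball_ang_rad = trajectory$ball_ang,
                   ball_angvel_radps = trajectory$ball_angvel,
                   phase_rad = trajectory$phase)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.delim(path)
  need <- c("time_s", "force_N", "cup_pos_m", "cup_vel_mps", "cup_acc_mps2",
            "ball_ang_rad", "ball_angvel_radps", "phase_rad")
  if (!all(need %in% names(df))) {
    stop("not a trajectory table: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- data.frame(time = df$time_s, cup_pos = df$cup_pos_m,
                    cup_vel = df$cup_vel_mps, cup_acc = df$cup_acc_mps2,
                    ball_ang = df$ball_ang_rad,
                    ball_angvel = df$ball_angvel_radps,
                    force = df$force_N, phase = df$phase_rad)
  new_trajectory(out, params = NULL)
}

metronome_sidecar <- function(path) sub("(\\.[^.]+)?$", "_metronome.tsv",
                                        path)

#' Write / read an experimental-style trial
#'
#' Trials use the trajectory table format (derivative channels written when
#' present, `NA` otherwise; the phase column is `NA`). Metronome beeps are
#' stored in a `_metronome.tsv` sidecar next to the trial file.
#'
#' @param trial A [trial_record()].
#' @param path Output file.
#' @return `write_trial` returns `path` invisibly; `read_trial` a
#'   [trial_record()].
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_record"))
  na <- rep(NA_real_, length(trial$time))
  df <- data.frame(time_s = trial$time, force_N = trial$force,
                   cup_pos_m = trial$cup_pos,
                   cup_vel_mps = if (is.null(trial$cup_vel)) na else trial$cup_vel,
                   cup_acc_mps2 = na,
                   ball_ang_rad = trial$ball_ang,
                   ball_angvel_radps = if (is.null(trial$ball_angvel)) na
                                       else trial$ball_angvel,
                   phase_rad = na)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (length(trial$metronome_times)) {
    utils::write.table(data.frame(beep_s = trial$metronome_times),
                       metronome_sidecar(path), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_trial
#' @param subject_id,trial_index Identifiers attached on read.
#' @export
read_trial <- function(path, subject_id = NA_character_,
                       trial_index = NA_integer_) {
  df <- utils::read.delim(path)
  beep_path <- metronome_sidecar(path)
  beeps <- if (file.exists(beep_path)) utils::read.delim(beep_path)$beep_s
           else NULL
  drop_all_na <- function(x) if (all(is.na(x))) NULL else x
  trial_record(time = df$time_s, force = df$force_N, cup_pos = df$cup_pos_m,
               ball_ang = df$ball_ang_rad,
               cup_vel = drop_all_na(df$cup_vel_mps),
               ball_angvel = drop_all_na(df$ball_angvel_radps),
               metronome_times = beeps,
               subject_id = subject_id, trial_index = trial_index)
}

#' Read a cohort manifest and its trials
#'
#' @param manifest_path Path to a tab-separated manifest with columns
#'   `subject_id`, `trial_index`, `path` (paths relative to the manifest's
#'   directory or absolute).
#' @return List with `manifest` and `trials` (nested by subject).
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.delim(manifest_path)
  stopifnot(all(c("subject_id", "trial_index", "path") %in% names(man)))
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  trials <- lapply(split(man, man$subject_id), function(d) {
    d <- d[order(d$trial_index), ]
    lapply(seq_len(nrow(d)), function(k) {
      read_trial(resolve(d$path[k]), d$subject_id[k], d$trial_index[k])
    })
  })
  list(manifest = man, trials = trials)
}
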