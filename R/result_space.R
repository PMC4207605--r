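#' Evaluate strategy measures over the (amplitude, ball-angle) result space
#'
#' Simulates every strategy on a rectangular grid of peak-to-peak cup
#' amplitude and initial ball angle, at fixed frequency and initial ball
#' angular velocity, and evaluates the requested strategy measures per cell.
#' The default grid covers the standard map domain (8-44 cm, +/- pi/2 rad)
#' at 1 cm by ~0.1 rad resolution. Failed cells are recorded as `NA` with a
#' logged reason instead of aborting the sweep; the sweep can be resumed
#' through a plain-text cache file.
#'
#' In addition to the per-cell measures, a `predictability_index` surface is
#' derived from the strobed-force variance, normalised per cell by the
#' strategy's own continuous-force variance (`pi_normalizer =
#' "force_variance"`, the default) or globally by the map's largest
#' strobed-force variance (`"map_max"`). The `jerk_ball_norm` surface uses
#' the cycle-amplitude jerk normalisation (see [mean_abs_jerk()]).
#'
#' @param amplitude_grid Peak-to-peak amplitudes (m).
#' @param theta0_grid Initial ball angles (rad).
#' @param frequency,omega0 Execution variables held fixed over the map
#'   (defaults 1 Hz, 0 rad/s).
#' @param params [model_params()].
#' @param measures Character subset of `"mi"`, `"gle"`, `"msf"`, `"jerk"`
#'   (all jerk variants), `"sal"`, `"strobe_var"`.
#' @param duration Simulated seconds per cell (45).
#' @param rate Sampling rate (Hz).
#' @param force_model Force convention.
#' @param gle_duration Horizon for the Lyapunov exponent (s).
#' @param pi_normalizer `"force_variance"` (default) or `"map_max"`.
#' @param cache Optional path to a TSV cache; completed cells are appended
#'   and reused when the call is repeated with the same grid settings.
#' @param progress Print one line per completed amplitude row.
#' @return An object of class `"measure_map"`: list with `amplitude_grid`,
#'   `theta0_grid`, `fixed_frequency`, `fixed_omega0`, `surfaces` (named
#'   list of `length(amplitude_grid)` x `length(theta0_grid)` matrices),
#'   `failures` (data frame), and `provenance`.
#' @examples
#' \donttest{
#' mp <- evaluate_result_space(seq(0.1, 0.3, by = 0.1),
#'                             seq(-1, 1, by = 1), measures = c("msf", "mi"))
#' measure_map_surface(mp, "msf")
#' }
#' @export
evaluate_result_space <- function(amplitude_grid = seq(0.08, 0.44, by = 0.01),
                                  theta0_grid = seq(-pi / 2, pi / 2,
                                                    length.out = 33),
                                  frequency = 1, omega0 = 0,
                                  params = model_params(),
                                  measures = c("mi", "gle", "msf", "jerk",
                                               "sal", "strobe_var"),
                                  duration = 45, rate = 120,
                                  force_model = "rendered",
                                  gle_duration = 60,
                                  pi_normalizer = c("force_variance", "map_max"),
                                  cache = NULL, progress = FALSE) {
  pi_normalizer <- match.arg(pi_normalizer)
  measures <- match.arg(measures, several.ok = TRUE)
  fields <- map_fields(measures)
  nA <- length(amplitude_grid); nT <- length(theta0_grid)
  surfaces <- stats::setNames(
    lapply(fields, function(f) matrix(NA_real_, nA, nT)), fields)
  failures <- data.frame(amplitude_pp = numeric(0), theta0 = numeric(0),
                         reason = character(0))
  cached <- read_map_cache(cache, fields)
  for (i in seq_len(nA)) {
    for (j in seq_len(nT)) {
      key <- cache_key(amplitude_grid[i], theta0_grid[j])
      if (!is.null(cached) && key %in% rownames(cached)) {
        for (f in fields) surfaces[[f]][i, j] <- cached[key, f]
        next
      }
      vals <- tryCatch(
        map_cell(amplitude_grid[i], theta0_grid[j], frequency, omega0,
                 params, measures, fields, duration, rate, force_model,
                 gle_duration),
        error = function(e) {
          failures[nrow(failures) + 1L, ] <<-
            list(amplitude_grid[i], theta0_grid[j], conditionMessage(e))
          stats::setNames(rep(NA_real_, length(fields)), fields)
        })
      for (f in fields) surfaces[[f]][i, j] <- vals[[f]]
      append_map_cache(cache, key, vals, fields)
    }
    if (progress) {
      message(sprintf("amplitude %d/%d (A = %.3f m) done", i, nA,
                      amplitude_grid[i]))
    }
  }
  if ("strobe_var" %in% fields) {
    norm <- if (pi_normalizer == "force_variance") surfaces$force_var
            else max(surfaces$strobe_var, na.rm = TRUE)
    surfaces$predictability_index <-
      pmin(pmax(1 - surfaces$strobe_var / norm, 0), 1)
  }
  structure(list(amplitude_grid = amplitude_grid, theta0_grid = theta0_grid,
                 fixed_frequency = frequency, fixed_omega0 = omega0,
                 surfaces = surfaces, failures = failures,
                 provenance = list(duration = duration, rate = rate,
                                   force_model = force_model,
                                   gle_duration = gle_duration,
                                   params = params,
                                   timestamp = format(Sys.time()))),
            class = "measure_map")
}

map_fields <- function(measures) {
  c(if ("mi" %in% measures) "mi",
    if ("gle" %in% measures) "gle",
    if ("msf" %in% measures) "msf",
    if ("jerk" %in% measures) c("jerk_ball_norm", "jerk_ball_raw",
                                "jerk_force_raw"),
    if ("sal" %in% measures) "sal",
    if ("strobe_var" %in% measures) c("strobe_var", "force_var"))
}

map_cell <- function(A, th0, frequency, omega0, params, measures, fields,
                     duration, rate, force_model, gle_duration) {
  s <- strategy(A, frequency, theta0 = th0, omega0 = omega0)
  tr <- simulate_strategy(s, params, duration, rate, force_model)
  vals <- stats::setNames(as.list(rep(NA_real_, length(fields))), fields)
  if ("mi" %in% measures) vals$mi <- mutual_information(tr$force, tr$phase)
  if ("gle" %in% measures) {
    vals$gle <- as.numeric(global_lyapunov(s, params, duration = gle_duration))
  }
  if ("msf" %in% measures) vals$msf <- mean_squared_force(tr$force)
  if ("jerk" %in% measures) {
    vals$jerk_ball_norm <- mean_abs_jerk(tr$ball_ang, rate,
                                         normalization = "cycle_amplitude",
                                         cycle_frequency = frequency)
    vals$jerk_ball_raw <- mean_abs_jerk(tr$ball_ang, rate, normalized = FALSE)
    vals$jerk_force_raw <- mean_abs_jerk(tr$force, rate, normalized = FALSE)
  }
  if ("sal" %in% measures) vals$sal <- spectral_arc_length(tr$ball_ang, rate)
  if ("strobe_var" %in% measures) {
    vals$strobe_var <- stats::var(strobe_at_cup_peaks(tr)$force_at_peak)
    vals$force_var <- stats::var(tr$force)
  }
  vals
}

cache_key <- function(A, th0) sprintf("%.6f_%.6f", A, th0)

read_map_cache <- function(cache, fields) {
  if (is.null(cache) || !file.exists(cache)) return(NULL)
  df <- utils::read.delim(cache, stringsAsFactors = FALSE)
  if (!all(fields %in% names(df))) return(NULL)
  rownames(df) <- df$key
  df
}

append_map_cache <- function(cache, key, vals, fields) {
  if (is.null(cache)) return(invisible(NULL))
  row <- data.frame(key = key, as.list(vals[fields]))
  utils::write.table(row, cache, sep = "\t", row.names = FALSE,
                     col.names = !file.exists(cache), append = file.exists(cache),
                     quote = FALSE)
}

#' @export
print.measure_map <- function(x, ...) {
  cat(sprintf("Result-space measure map: %d x %d cells (A %.3g-%.3g m pp, theta0 %.3g-%.3g rad)\n",
              length(x$amplitude_grid), length(x$theta0_grid),
              min(x$amplitude_grid), max(x$amplitude_grid),
              min(x$theta0_grid), max(x$theta0_grid)))
  cat(sprintf("  fixed: f = %.3g Hz, omega0 = %.3g rad/s\n",
              x$fixed_frequency, x$fixed_omega0))
  cat(sprintf("  surfaces: %s\n", paste(names(x$surfaces), collapse = ", ")))
  if (nrow(x$failures)) cat(sprintf("  %d failed cells\n", nrow(x$failures)))
  invisible(x)
}

#' Extract one surface of a measure map
#'
#' @param map A `"measure_map"`.
#' @param measure Surface name (e.g. `"mi"`, `"gle"`, `"msf"`,
#'   `"jerk_ball_norm"`, `"predictability_index"`).
#' @return Matrix of `length(amplitude_grid)` rows by `length(theta0_grid)`
#'   columns, with the grids as dimnames.
#' @export
measure_map_surface <- function(map, measure) {
  stopifnot(inherits(map, "measure_map"))
  if (!measure %in% names(map$surfaces)) {
    stop(sprintf("surface '%s' not present (have: %s)", measure,
                 paste(names(map$surfaces), collapse = ", ")))
  }
  m <- map$surfaces[[measure]]
  dimnames(m) <- list(format(map$amplitude_grid), format(map$theta0_grid))
  m
}

#' Long-format table of a measure map
#'
#' @param x A `"measure_map"`.
#' @param ... Unused.
#' @return Data frame with `amplitude_pp_m`, `theta0_rad`, `measure`,
#'   `value`.
#' @export
as.data.frame.measure_map <- function(x, ...) {
  do.call(rbind, lapply(names(x$surfaces), function(f) {
    data.frame(amplitude_pp_m = rep(x$amplitude_grid,
                                    times = length(x$theta0_grid)),
               theta0_rad = rep(x$theta0_grid, each = length(x$amplitude_grid)),
               measure = f, value = as.vector(x$surfaces[[f]]))
  }))
}

#' Locate a criterion's optimal strategy on a measure map
#'
#' Grid argument-optimum of one of the four selection criteria: maximum
#' mutual information (predictability), minimum mean squared force (effort),
#' minimum Lyapunov exponent, or minimum normalised ball jerk (smoothness).
#' Ties are broken toward larger amplitude, then larger ball angle.
#'
#' @param map A `"measure_map"`.
#' @param criterion One of `"max_mi"`, `"min_msf"`, `"min_gle"`,
#'   `"min_norm_jerk"`.
#' @return List with `strategy` (a [strategy()] at the optimal cell),
#'   `value`, and the grid `indices`.
#' @export
locate_optima <- function(map, criterion = c("max_mi", "min_msf", "min_gle",
                                             "min_norm_jerk")) {
  criterion <- match.arg(criterion)
  surf_name <- switch(criterion, max_mi = "mi", min_msf = "msf",
                      min_gle = "gle", min_norm_jerk = "jerk_ball_norm")
  m <- measure_map_surface(map, surf_name)
  if (all(is.na(m))) stop(sprintf("surface '%s' is entirely NA", surf_name))
  score <- if (criterion == "max_mi") m else -m
  best <- max(score, na.rm = TRUE)
  hits <- which(score == best, arr.ind = TRUE)
  # tie-break toward larger amplitude (row), then larger theta0 (col)
  hits <- hits[order(-hits[, 1L], -hits[, 2L]), , drop = FALSE]
  i <- hits[1L, 1L]; j <- hits[1L, 2L]
  list(strategy = strategy(map$amplitude_grid[i], map$fixed_frequency,
                           theta0 = map$theta0_grid[j],
                           omega0 = map$fixed_omega0),
       value = m[i, j], indices = c(amplitude = i, theta0 = j))
}

#' Bilinear lookup of a map surface at an arbitrary strategy
#'
#' Interpolates one surface at a (possibly off-grid) amplitude/ball-angle
#' point. Points outside the grid are clipped to its boundary, with a
#' warning.
#'
#' @param map A `"measure_map"`.
#' @param measure Surface name.
#' @param amplitude_pp Peak-to-peak amplitude (m).
#' @param theta0 Ball angle (rad).
#' @return Interpolated value (scalar).
#' @export
map_lookup <- function(map, measure, amplitude_pp, theta0) {
  m <- measure_map_surface(map, measure)
  Ag <- map$amplitude_grid; Tg <- map$theta0_grid
  if (amplitude_pp < min(Ag) || amplitude_pp > max(Ag) ||
      theta0 < min(Tg) || theta0 > max(Tg)) {
    warning(sprintf("lookup point (%.3g m, %.3g rad) clipped to the map domain",
                    amplitude_pp, theta0))
  }
  A <- min(max(amplitude_pp, min(Ag)), max(Ag))
  th <- min(max(theta0, min(Tg)), max(Tg))
  i <- findInterval(A, Ag, all.inside = TRUE)
  j <- findInterval(th, Tg, all.inside = TRUE)
  u <- (A - Ag[i]) / (Ag[i + 1L] - Ag[i])
  v <- (th - Tg[j]) / (Tg[j + 1L] - Tg[j])
  (1 - u) * (1 - v) * m[i, j] + u * (1 - v) * m[i + 1L, j] +
    (1 - u) * v * m[i, j + 1L] + u * v * m[i + 1L, j + 1L]
}
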