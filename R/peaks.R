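#' Detect cycle extrema of a rhythmic cup-position signal
#'
#' Finds the local maxima and minima that delimit movement cycles in a
#' (possibly noisy) cup-position recording. The signal is first low-pass
#' filtered for detection (zero-phase Butterworth, cutoff five times the
#' nominal cycle frequency by default) so sensor noise cannot spawn
#' spurious extrema; a clean sinusoid passes through unchanged to within
#' filter precision. Candidate extrema are sign changes of the first
#' difference; candidates closer than half the nominal period keep only the
#' most extreme; maxima and minima are then forced to alternate (runs of
#' the same kind keep their most extreme member) and a prominence rule
#' discards wiggles smaller than a quarter of the running peak-to-peak
#' amplitude (the local amplitude in a window of two nominal periods).
#' Extremum times and values are refined by a parabolic fit through the
#' three filtered samples around each extremum. Samples at the ends of the
#' record count as extrema when the signal turns there, so a peak-aligned
#' record keeps its boundary peaks.
#'
#' @param cup_pos Numeric signal (m).
#' @param rate Sampling rate (Hz).
#' @param nominal_f Nominal cycle frequency (Hz); sets the minimum extremum
#'   separation `0.5 / nominal_f`.
#' @param smooth_cutoff Detection filter cutoff (Hz); `NULL` disables the
#'   filtering.
#' @return A list of class `"cycle_peaks"` with data frames `maxima` and
#'   `minima`, each with columns `index` (sample index of the raw extremum),
#'   `time` (refined, s) and `value` (refined signal value).
#' @examples
#' tt <- seq(0, 45, by = 1 / 120)
#' pk <- detect_cycle_peaks(0.1 * cos(2 * pi * tt), rate = 120, nominal_f = 1)
#' nrow(pk$maxima)  # 46: one per cycle plus both boundary peaks
#' @export
detect_cycle_peaks <- function(cup_pos, rate, nominal_f = 1,
                               smooth_cutoff = 5 * nominal_f) {
  n <- length(cup_pos)
  if (n < 3 * rate / nominal_f) stop("need at least 3 nominal cycles of data")
  if (stats::sd(cup_pos) == 0) stop("no extrema detected (constant signal)")
  x <- cup_pos
  if (!is.null(smooth_cutoff) && smooth_cutoff < rate / 2) {
    # mirror-pad so the zero-phase filter has no edge transients, which
    # would otherwise destroy boundary extrema
    p <- min(n - 1L, ceiling(2 * rate / nominal_f))
    padded <- c(cup_pos[(p + 1L):2L], cup_pos, cup_pos[(n - 1L):(n - p)])
    bf <- signal::butter(4, smooth_cutoff / (rate / 2), type = "low")
    xs <- signal::filtfilt(bf, padded)
    x <- xs[(p + 1L):(p + n)]
  }
  d <- diff(x)
  sgn <- sign(d)
  sgn[sgn == 0] <- 1          # flat segments counted with the rising side
  turn <- diff(sgn)
  max_idx <- which(turn < 0) + 1L
  min_idx <- which(turn > 0) + 1L
  # boundary samples: the signal may start or end on an extremum; a boundary
  # sample only qualifies when it comes close to the local extreme level, so
  # a record that merely ends mid-rise does not fabricate a peak
  win <- round(rate / nominal_f)
  near_extreme <- function(i, sgn) {
    w <- x[max(1L, i - win):min(n, i + win)]
    sgn * x[i] >= max(sgn * w) - 0.05 * diff(range(w))
  }
  if (x[1L] > x[2L] && near_extreme(1L, +1)) max_idx <- c(1L, max_idx)
  if (x[1L] < x[2L] && near_extreme(1L, -1)) min_idx <- c(1L, min_idx)
  if (x[n] > x[n - 1L] && near_extreme(n, +1)) max_idx <- c(max_idx, n)
  if (x[n] < x[n - 1L] && near_extreme(n, -1)) min_idx <- c(min_idx, n)
  if (length(max_idx) == 0L && length(min_idx) == 0L) {
    stop("no extrema detected (constant signal?)")
  }
  min_sep <- 0.5 / nominal_f * rate
  max_idx <- enforce_separation(max_idx, x, min_sep)
  min_idx <- enforce_separation(min_idx, -x, min_sep)
  alt <- enforce_alternation(max_idx, min_idx, x)
  max_idx <- alt$max_idx; min_idx <- alt$min_idx
  # prominence: at least 25% of the running peak-to-peak amplitude
  half_win <- round(rate / nominal_f)   # one nominal period each side
  local_pp <- function(i) {
    lo <- max(1L, i - half_win); hi <- min(n, i + half_win)
    diff(range(x[lo:hi]))
  }
  keep_prominent <- function(idx, other_idx, sgn) {
    keep <- logical(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      left <- other_idx[other_idx < i]
      right <- other_idx[other_idx > i]
      ref <- c(if (length(left)) x[max(left)], if (length(right)) x[min(right)])
      prom <- if (length(ref)) min(sgn * (x[i] - ref)) else local_pp(i)
      keep[k] <- prom >= 0.25 * local_pp(i)
    }
    idx[keep]
  }
  max_idx <- keep_prominent(max_idx, min_idx, +1)
  min_idx <- keep_prominent(min_idx, max_idx, -1)
  if (length(max_idx) < 2L) stop("fewer than 2 maxima detected")
  refine <- function(idx) {
    out <- data.frame(index = idx, time = (idx - 1L) / rate, value = x[idx])
    interior <- idx > 1L & idx < n
    for (k in which(interior)) {
      i <- idx[k]
      y <- x[(i - 1L):(i + 1L)]
      denom <- y[1L] - 2 * y[2L] + y[3L]
      if (abs(denom) > .Machine$double.eps) {
        delta <- 0.5 * (y[1L] - y[3L]) / denom
        delta <- max(min(delta, 0.5), -0.5)
        out$time[k] <- (i - 1L + delta) / rate
        out$value[k] <- y[2L] - 0.25 * (y[1L] - y[3L]) * delta
      }
    }
    out
  }
  structure(list(maxima = refine(max_idx), minima = refine(min_idx),
                 rate = rate, nominal_f = nominal_f),
            class = "cycle_peaks")
}

# keep only candidates separated by at least min_sep samples, preferring the
# larger value of `score`
enforce_separation <- function(idx, score, min_sep) {
  if (length(idx) <= 1L) return(idx)
  ord <- idx[order(score[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

# force maxima and minima to alternate: a run of same-kind extrema keeps
# only its most extreme member
enforce_alternation <- function(max_idx, min_idx, x) {
  idx <- c(max_idx, min_idx)
  kind <- rep(c(1L, -1L), c(length(max_idx), length(min_idx)))
  o <- order(idx)
  idx <- idx[o]; kind <- kind[o]
  keep <- logical(length(idx))
  i <- 1L
  while (i <= length(idx)) {
    j <- i
    while (j < length(idx) && kind[j + 1L] == kind[i]) j <- j + 1L
    run <- i:j
    best <- run[which.max(kind[i] * x[idx[run]])]
    keep[best] <- TRUE
    i <- j + 1L
  }
  list(max_idx = idx[keep & kind == 1L], min_idx = idx[keep & kind == -1L])
}

#' @export
print.cycle_peaks <- function(x, ...) {
  cat(sprintf("Cycle extrema: %d maxima, %d minima (nominal %.3g Hz)\n",
              nrow(x$maxima), nrow(x$minima), x$nominal_f))
  invisible(x)
}
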