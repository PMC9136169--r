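# Signal preprocessing: filter, RSS, heel strikes, cycle segmentation ----

#' Zero-phase low-pass Butterworth filter
#'
#' Applies an `order`-th order low-pass Butterworth filter forward and
#' backward (zero phase), so heel-strike valleys are smoothed but not
#' delayed. Because the filter runs twice, the effective magnitude response
#' is the square of the single-pass response.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param order Filter order (single pass). Default 8.
#' @param cutoff Cut-off frequency, Hz. Default 20. Must be below the
#'   Nyquist frequency `fs / 2`.
#' @return Filtered series of the same length.
#' @export
#' @examples
#' t <- (0:599) / 120
#' x <- sin(2 * pi * 5 * t) + 0.2 * sin(2 * pi * 45 * t)
#' y <- lowpass_filter(x, fs = 120)
lowpass_filter <- function(x, fs, order = 8, cutoff = 20) {
  if (!is.numeric(x) || !all(is.finite(x))) abort("`x` must be finite numeric")
  if (cutoff >= fs / 2) {
    abort(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)", cutoff, fs / 2))
  }
  if (length(x) <= 3 * (order + 1)) {
    abort(sprintf("series too short to filter: %d samples, need > %d", length(x), 3 * (order + 1)))
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection padding suppresses the forward-backward pass's edge
  # transients (and preserves DC exactly at the boundaries)
  n <- length(x)
  pad <- min(10L * (order + 1L), n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  yp[(pad + 1):(pad + n)]
}

#' Root sum of squares of a tri-axial signal
#'
#' Per-sample magnitude `sqrt(ax^2 + ay^2 + az^2)` of the acceleration
#' vector. The result is directionless: it is invariant under any
#' permutation or sign flip of the axes, which removes the sensor-orientation
#' dependence of the individual components.
#'
#' @param ax,ay,az Numeric series of equal length (g).
#' @return Nonnegative numeric series of the same length.
#' @export
#' @examples
#' compute_rss(3, 4, 0)
compute_rss <- function(ax, ay, az) {
  if (length(ay) != length(ax) || length(az) != length(ax)) {
    abort("axis series must have equal length")
  }
  if (!all(is.finite(ax), is.finite(ay), is.finite(az))) {
    abort("axis series must be finite")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' Detect heel strikes from anterior-posterior ankle acceleration
#'
#' Heel strikes appear as pronounced valleys in the (filtered) x-axis series
#' of an ankle sensor. Candidates are local minima deeper than
#' `mean(x) - depth_sd * sd(x)`; candidates closer together than
#' `min_separation_s` are resolved in favor of the deeper valley.
#'
#' @param x Filtered anterior-posterior acceleration series of one ankle.
#' @param fs Sampling rate, Hz.
#' @param min_separation_s Minimum time between consecutive heel strikes of
#'   the same foot, seconds. Default 0.5 s.
#' @param depth_sd Valley-depth threshold in SD units below the series mean.
#' @return Strictly increasing integer vector of heel-strike sample indices
#'   (1-based).
#' @details Minima closer than `min_separation_s / 2` to either end of the
#'   series are ignored: a heel strike cannot be confirmed against the
#'   recording boundary, and zero-phase filter startup transients live
#'   there.
#' @export
detect_heel_strikes <- function(x, fs, min_separation_s = 0.5, depth_sd = 0.5) {
  if (length(x) < 3) abort("insufficient gait cycles: series too short")
  n <- length(x)
  edge <- round(min_separation_s / 2 * fs)
  inner <- (max(2, 1 + edge)):(min(n - 1, n - edge))
  if (length(inner) < 1) abort("insufficient gait cycles: series too short")
  is_min <- x[inner] < x[inner - 1] & x[inner] <= x[inner + 1]
  thr <- mean(x) - depth_sd * sd(x)
  cand <- inner[is_min & x[inner] < thr]
  if (length(cand) >= 2) {
    min_gap <- min_separation_s * fs
    keep <- integer(0)
    for (i in cand[order(x[cand])]) {    # deepest first
      if (all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
    }
    cand <- sort(keep)
  }
  if (length(cand) < 2) {
    abort(sprintf("insufficient gait cycles: %d heel strike(s) detected, need >= 2",
                  length(cand)))
  }
  cand
}

#' Segment a series into gait cycles at heel strikes
#'
#' Each consecutive pair of heel strikes bounds one gait cycle, half-open
#' `[strike_i, strike_{i+1})`, so the cycles tile the inter-strike span with
#' no gaps or overlaps and `n_cycles = n_strikes - 1`.
#'
#' @param x Numeric series (one source: an axis component or the RSS).
#' @param strikes Increasing heel-strike sample indices (1-based).
#' @return A tibble with one row per cycle: `cycle`, `start` (inclusive),
#'   `end` (exclusive), `n`, and `samples` (list column).
#' @export
segment_cycles <- function(x, strikes) {
  if (length(strikes) < 2) abort("insufficient gait cycles: need >= 2 heel strikes")
  if (is.unsorted(strikes, strictly = TRUE)) abort("`strikes` must be strictly increasing")
  if (strikes[1] < 1 || strikes[length(strikes)] > length(x)) {
    abort("heel-strike indices outside the series")
  }
  n_cyc <- length(strikes) - 1L
  tibble::tibble(
    cycle = seq_len(n_cyc),
    start = strikes[-length(strikes)],
    end = strikes[-1],
    n = strikes[-1] - strikes[-length(strikes)],
    samples = lapply(seq_len(n_cyc), function(i) {
      x[strikes[i]:(strikes[i + 1] - 1L)]
    })
  )
}

#' Select the middle n gait cycles of a trial
#'
#' The strides at the start and end of a walkway pass carry acceleration and
#' deceleration transients, so the analysis uses the five midsection strides.
#' The selection keeps `n` consecutive cycles centered in the list, starting
#' at offset `floor((len - n) / 2)`.
#'
#' @param cycles Cycle tibble from [segment_cycles()].
#' @param n Number of cycles to keep. Default 5.
#' @return The selected rows, order preserved.
#' @export
select_midsection_cycles <- function(cycles, n = 5) {
  len <- nrow(cycles)
  if (len < n) {
    abort(sprintf("trial too short: %d gait cycles available, %d required", len, n))
  }
  start0 <- floor((len - n) / 2)
  cycles[(start0 + 1):(start0 + n), ]
}

#' Time-normalize a gait cycle to a fixed length
#'
#' Resamples one cycle to `L` points (0--100% of the cycle) by linear
#' interpolation, removing stride-duration differences so cycles can be
#' compared point by point.
#'
#' @param samples Numeric samples of one cycle (>= 4 samples).
#' @param L Normalized length. Default 100 points.
#' @return Numeric vector of length `L`; the first sample is preserved
#'   exactly.
#' @export
normalize_cycle_length <- function(samples, L = 100) {
  if (L < 2) abort("`L` must be >= 2")
  m <- length(samples)
  if (m < 4) abort(sprintf("cycle too short to resample: %d samples", m))
  if (m == L) return(as.numeric(samples))
  approx(seq(0, 1, length.out = m), samples, xout = seq(0, 1, length.out = L))$y
}

# map a source name to the per-side filtered series
source_series <- function(sig_f, source, side) {
  col <- switch(side, left = c(x = "lx", y = "ly", z = "lz"),
                right = c(x = "rx", y = "ry", z = "rz"))
  if (source == "rss") {
    compute_rss(sig_f[[col[["x"]]]], sig_f[[col[["y"]]]], sig_f[[col[["z"]]]])
  } else {
    sig_f[[col[[source]]]]
  }
}

#' Preprocess one gait trial into normalized midsection cycles
#'
#' Runs the full preprocessing chain for one trial: per-axis zero-phase
#' low-pass filtering, RSS computation, heel-strike detection on each side's
#' filtered x-axis, cycle segmentation of the requested source series,
#' midsection selection, and time normalization. Trials that cannot supply
#' `n_cycles + 2` segmented cycles per side (midsection selection with a
#' one-stride margin) are rejected with a diagnostic error.
#'
#' @param trial One-row cohort tibble from [simulate_trial()] /
#'   [simulate_cohort()] (or [read_cohort()]).
#' @param source Signal source: `"x"`, `"y"`, `"z"`, or `"rss"`.
#' @param n_cycles Number of midsection cycles. Default 5.
#' @param L Normalized cycle length. Default 100.
#' @param filter_order,cutoff_hz Butterworth settings; see
#'   [lowpass_filter()].
#' @param min_separation_s,depth_sd Heel-strike detector settings; see
#'   [detect_heel_strikes()].
#' @return A list with `left` and `right` (`n_cycles` x `L` matrices of
#'   normalized cycles), the detected `strikes_left`/`strikes_right`, and
#'   `qc` (a one-row tibble of per-trial quality-control counts).
#' @export
preprocess_trial <- function(trial, source = "rss", n_cycles = 5, L = 100,
                             filter_order = 8, cutoff_hz = 20,
                             min_separation_s = 0.5, depth_sd = 0.5) {
  source <- match.arg(source, c("x", "y", "z", "rss"))
  sig <- trial$signal[[1]]
  fs <- trial$fs[[1]]
  sig_f <- sig
  for (col in c("lx", "ly", "lz", "rx", "ry", "rz")) {
    sig_f[[col]] <- lowpass_filter(sig[[col]], fs, filter_order, cutoff_hz)
  }
  strikes <- lapply(c(left = "lx", right = "rx"), function(col) {
    detect_heel_strikes(sig_f[[col]], fs, min_separation_s, depth_sd)
  })
  min_required <- n_cycles + 2L
  sides <- lapply(c(left = "left", right = "right"), function(side) {
    cyc <- segment_cycles(source_series(sig_f, source, side), strikes[[side]])
    if (nrow(cyc) < min_required) {
      abort(sprintf(
        "trial %s/%s too short on %s side: %d cycles segmented, %d required",
        trial$participant_id[[1]], trial$trial_id[[1]], side, nrow(cyc), min_required
      ))
    }
    sel <- select_midsection_cycles(cyc, n_cycles)
    mat <- t(vapply(sel$samples, normalize_cycle_length,
                    FUN.VALUE = numeric(L), L = L))
    list(cycles = mat, selected = sel$cycle)
  })
  list(
    left = sides$left$cycles,
    right = sides$right$cycles,
    strikes_left = strikes$left,
    strikes_right = strikes$right,
    qc = tibble::tibble(
      participant_id = trial$participant_id[[1]],
      trial_id = trial$trial_id[[1]],
      source = source,
      n_strikes_left = length(strikes$left),
      n_strikes_right = length(strikes$right),
      selected_first = sides$left$selected[1],
      selected_last = sides$left$selected[n_cycles]
    )
  )
}
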