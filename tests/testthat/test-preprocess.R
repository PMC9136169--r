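# measure the steady-state gain of the zero-phase filter at one frequency
# by regressing the filtered sinusoid on sine/cosine after trimming edges
measured_gain <- function(f, fs = 120, n = 1200, trim = 240) {
  t <- (0:(n - 1)) / fs
  y <- lowpass_filter(sin(2 * pi * f * t), fs)
  idx <- (trim + 1):(n - trim)
  fit <- lm.fit(cbind(sin(2 * pi * f * t[idx]), cos(2 * pi * f * t[idx])),
                y[idx])
  sqrt(sum(fit$coefficients^2))
}

test_that("zero-phase Butterworth filter matches its analytic magnitude response", {
  # squared single-pass response because the filter runs forward and
  # backward; the digital response follows the bilinear-warped curve
  analytic <- function(f, fs = 120, fc = 20, order = 8) {
    1 / (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * order))
  }
  for (f in c(2, 5, 10, 15)) {
    expect_equal(measured_gain(f), analytic(f), tolerance = 1e-3)
  }
  # half-power point of the squared response at the cutoff
  expect_equal(measured_gain(20), 0.5, tolerance = 1e-3)
  # deep stopband: 40 Hz attenuated to at most 1e-4 of the input
  expect_lt(measured_gain(40), 1e-4)
})

test_that("filtering preserves DC, length, and valley timing", {
  expect_equal(lowpass_filter(rep(2.5, 500), 120), rep(2.5, 500),
               tolerance = 1e-8)
  x <- rnorm(777)
  expect_length(lowpass_filter(x, 120), 777)

  # zero-phase: the filtered noiseless valley stays on its sample
  tr <- simulate_trial(clean_profile(), seed = 1)
  xf <- lowpass_filter(tr$signal[[1]]$lx, 120)
  h2 <- tr$hs_left[[1]][2]
  win <- (h2 - 60):(h2 + 60)
  expect_identical(win[which.min(xf[win])], h2)

  expect_error(lowpass_filter(x, fs = 30, cutoff = 20), "Nyquist")
  expect_error(lowpass_filter(x[1:10], 120), "too short")
})

test_that("RSS is the per-sample vector magnitude and is orientation-invariant", {
  expect_equal(compute_rss(3, 4, 0), 5)
  expect_equal(compute_rss(0, 0, 0), 0)
  expect_equal(compute_rss(1, 1, 1), sqrt(3))
  expect_error(compute_rss(1:3, 1:2, 1:3), "equal length")

  set.seed(4)
  ax <- rnorm(50); ay <- rnorm(50); az <- rnorm(50)
  base <- compute_rss(ax, ay, az)
  for (perm in list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))) {
    axes <- list(ax, ay, az)[perm]
    signs <- sample(c(-1, 1), 3, replace = TRUE)
    expect_equal(compute_rss(signs[1] * axes[[1]], signs[2] * axes[[2]],
                             signs[3] * axes[[3]]), base)
  }
})

test_that("heel strikes are recovered exactly in noiseless mode and within 2 samples under jitter", {
  tr <- simulate_trial(clean_profile(), seed = 1)
  sig <- tr$signal[[1]]
  expect_identical(detect_heel_strikes(lowpass_filter(sig$lx, 120), 120),
                   tr$hs_left[[1]])
  expect_identical(detect_heel_strikes(lowpass_filter(sig$rx, 120), 120),
                   tr$hs_right[[1]])

  # noiseless trials with stride-timing jitter: strikes land off the ideal
  # grid, detection recovers them to within 2 samples
  jittered <- gait_profile(cycle_duration_s = 1.05, amplitude_jitter = 0,
                           timing_jitter = 0.05, asymmetry_amp = 0,
                           asymmetry_phase = 0, noise_sd = 0, mounting_sd = 0,
                           walk_duration_s = 8.43)
  for (s in 1:20) {
    trj <- simulate_trial(jittered, seed = s)
    sigj <- trj$signal[[1]]
    for (side in c("l", "r")) {
      det <- detect_heel_strikes(lowpass_filter(sigj[[paste0(side, "x")]], 120), 120)
      truth <- if (side == "l") trj$hs_left[[1]] else trj$hs_right[[1]]
      expect_length(det, length(truth))
      expect_lte(max(abs(det - truth)), 2)
    }
  }

  # at the noisy study defaults every trial still yields enough strikes for
  # the five midsection strides on both sides
  for (profile in list(nonfaller_profile(), faller_profile())) {
    for (s in 1:10) {
      trj <- simulate_trial(profile, seed = s)
      sigj <- trj$signal[[1]]
      for (side in c("l", "r")) {
        det <- detect_heel_strikes(lowpass_filter(sigj[[paste0(side, "x")]], 120), 120)
        expect_gte(length(det), 8)
      }
    }
  }
})

test_that("detection rejects signals without plausible valleys", {
  expect_error(detect_heel_strikes(seq(0, 1, length.out = 500), 120),
               "insufficient gait cycles")
  expect_error(detect_heel_strikes(rep(1, 500), 120), "insufficient gait cycles")
})

test_that("segmentation tiles the inter-strike span half-open with no gaps", {
  x <- rnorm(400)
  cyc <- segment_cycles(x, c(100L, 220L, 341L))
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$n, c(120, 121))
  expect_equal(cyc$samples[[1]], x[100:219])
  expect_equal(cyc$samples[[2]], x[220:340])
  # partition property: concatenation reproduces the span exactly
  expect_identical(unlist(cyc$samples), x[100:340])

  strikes11 <- as.integer(seq(10, 310, by = 30))
  expect_equal(nrow(segment_cycles(rnorm(320), strikes11)), 10)
  expect_error(segment_cycles(x, c(100L)), "insufficient")
  expect_error(segment_cycles(x, c(100L, 90L, 200L)), "strictly increasing")
})

test_that("midsection selection keeps n consecutive centered cycles", {
  cyc <- segment_cycles(rnorm(1300), as.integer(seq(1, 1201, by = 120)))
  expect_equal(nrow(cyc), 10)
  sel <- select_midsection_cycles(cyc, 5)
  expect_equal(sel$cycle, 3:7)     # 0-based offset floor((10-5)/2) = 2
  sel5 <- select_midsection_cycles(cyc[1:5, ], 5)
  expect_equal(sel5$cycle, 1:5)
  expect_error(select_midsection_cycles(cyc[1:4, ], 5), "too short")
})

test_that("cycle time-normalization is exact on affine inputs and accurate on smooth ones", {
  ramp <- seq(0, 1, length.out = 73)
  out <- normalize_cycle_length(ramp, 100)
  expect_equal(out, seq(0, 1, length.out = 100), tolerance = 1e-12)

  v <- rnorm(100)
  expect_identical(normalize_cycle_length(v, 100), v)

  s <- sin(2 * pi * (0:119) / 120)
  out <- normalize_cycle_length(s, 100)
  truth <- sin(2 * pi * seq(0, 119, length.out = 100) / 120)
  expect_lt(max(abs(out - truth)), 0.002)
  expect_equal(out[1], s[1])

  expect_error(normalize_cycle_length(1:3, 100), "too short")
  expect_error(normalize_cycle_length(rnorm(10), 1), "L")
})

test_that("preprocess_trial returns five normalized cycles per side with QC", {
  tr <- simulate_trial(nonfaller_profile(), seed = 5)
  pre <- preprocess_trial(tr, source = "rss")
  expect_equal(dim(pre$left), c(5, 100))
  expect_equal(dim(pre$right), c(5, 100))
  expect_true(all(pre$left >= 0))
  expect_equal(pre$qc$n_strikes_left, length(pre$strikes_left))

  short <- simulate_trial(clean_profile(walk_duration_s = 3), seed = 1)
  # stride-count floor still guarantees enough cycles even for short walks
  expect_silent(preprocess_trial(short, source = "x"))
})
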