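# Synthetic bilateral ankle accelerometry --------------------------------

# Per-axis waveform template: each gait cycle is a sum of wrapped Gaussian
# bursts over cycle phase in [0, 1). The anterior-posterior (x) axis carries
# one deep negative burst exactly at heel strike (phase 0), which is what the
# heel-strike detector keys on; toe-off and swing bursts are placed relative
# to the stance fraction. Amplitudes are in g, in the +/-2 g range.
gait_waveform_template <- function(stance_fraction) {
  sf <- stance_fraction
  # shiftable: stance/swing bursts whose within-cycle timing drifts;
  # mobile: the vertical loading spike, whose timing relative to heel
  # strike varies with gait quality while the x valley stays anchored at
  # the heel-strike instant (it defines the event)
  tibble::tribble(
    ~axis, ~center,        ~width, ~amp,  ~shiftable, ~mobile,
    "x",   0.000,          0.025,  -2.00, FALSE,      FALSE,
    "x",   sf,             0.060,   0.90, TRUE,       FALSE,
    "x",   (1 + sf) / 2,   0.090,   0.55, TRUE,       FALSE,
    "y",   0.140,          0.050,   0.45, TRUE,       FALSE,
    "y",   sf,             0.080,  -0.20, TRUE,       FALSE,
    "y",   0.820,          0.100,   0.30, TRUE,       FALSE,
    "z",   0.045,          0.030,   1.30, FALSE,      TRUE,
    "z",   sf,             0.070,   0.65, TRUE,       FALSE,
    "z",   0.880,          0.090,  -0.45, TRUE,       FALSE
  )
}

# vertical axis rides on a ~1 g gravity baseline
.axis_baseline <- c(x = 0, y = 0, z = 1)

wrapped_gaussian <- function(phase, center, width) {
  exp(-0.5 * ((phase - center) / width)^2) +
    exp(-0.5 * ((phase - center + 1) / width)^2) +
    exp(-0.5 * ((phase - center - 1) / width)^2)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# fixed phases of the orthogonal shape direction per axis (see
# orthogonal_shape below), and per-axis attenuation of the shape-rotation
# angle: anterior-posterior ankle motion is mechanically constrained by the
# walking direction, so gait-quality shape changes express more strongly in
# the medio-lateral and vertical channels
.q_phase <- c(x = 0.2, y = 2.5, z = 4.5)

# SD (radians) of the per-trial strap-mounting rotation about the vertical
# axis: re-strapping the sensor never reproduces the anterior-posterior
# orientation exactly, so the x and y channels mix a little from trial to
# trial. The RSS magnitude is exactly invariant under this rotation, which
# is the reason the directionless source is preferred for classification.
.mount_sd <- 0.5
.rot_atten <- c(x = 0.15, y = 1.0, z = 1.0)
.shift_atten <- c(x = 0.15, y = 1.0, z = 1.0)

# Orthogonal equal-variance shape direction for one axis of a template:
# a single-harmonic waveform made orthogonal (over cycle phase) to the
# axis's stance/swing (shiftable) burst component and rescaled to its
# standard deviation. Rotating that component toward this direction changes
# the waveform's shape at controlled correlation cos(angle) with the
# unrotated cycle while preserving its variance -- which keeps the NCC
# series' normalization uniform -- and leaves the impact transients (the
# detection anchors) untouched.
orthogonal_shape <- function(template, ax) {
  rows <- which(template$axis == ax & template$shiftable)
  grid <- (0:511) / 512
  w <- rep(0, 512)
  for (b in rows) {
    w <- w + template$amp[b] *
      wrapped_gaussian(grid, template$center[b], template$width[b])
  }
  w0 <- w - mean(w)
  sgrid <- sin(2 * pi * grid + .q_phase[[ax]])
  s0 <- sgrid - mean(sgrid)
  chat <- sum(s0 * w0) / sum(w0^2)
  q0 <- s0 - chat * w0
  lambda <- sqrt(sum(w0^2) / sum(q0^2))
  list(k1 = lambda, k2 = lambda * chat)
}

# Evaluate one leg's tri-axial signal on the global sample grid.
# h: heel-strike times (s), already snapped to the sample grid; durs: matched
# cycle durations; amp_mult / ctr_shift / wid_mult: (n_cycles_extended x
# n_bumps) per-cycle burst jitters; imp_shift: per-cycle timing scatter of
# the mobile (vertical loading) spike; ang: per-cycle shape-rotation angle
# toward the axis's orthogonal direction (see orthogonal_shape).
eval_leg_signal <- function(t, h, durs, template, amp_mult, ctr_shift,
                            wid_mult, imp_shift, ang, qcoef, noise_sd,
                            T0) {
  n <- length(h)
  hh <- c(h[1] - T0, h, h[n] + durs[n], h[n] + durs[n] + T0)
  k <- findInterval(t, hh)
  k <- clamp(k, 1L, length(hh) - 1L)
  phase <- (t - hh[k]) / (hh[k + 1] - hh[k])
  out <- list()
  for (ax in c("x", "y", "z")) {
    cosang <- cos(.rot_atten[[ax]] * ang)[k]
    sinang <- sin(.rot_atten[[ax]] * ang)[k]
    rows <- which(template$axis == ax)
    burst_fix <- rep(0, length(t))
    burst_rot <- rep(0, length(t))
    base_rot <- rep(0, length(t))
    for (j in seq_along(rows)) {
      b <- rows[j]
      ctr <- template$center[b] +
        (if (template$shiftable[b]) .shift_atten[[ax]] * ctr_shift[k, b] else 0) +
        (if (template$mobile[b]) imp_shift[k] else 0)
      bump <- template$amp[b] * amp_mult[k, b] *
        wrapped_gaussian(phase, ctr, template$width[b] * wid_mult[k, b])
      if (template$shiftable[b]) {
        burst_rot <- burst_rot + bump
        base_rot <- base_rot + template$amp[b] *
          wrapped_gaussian(phase, template$center[b], template$width[b])
      } else {
        burst_fix <- burst_fix + bump
      }
    }
    qc <- qcoef[[ax]]
    qval <- qc$k1 * sin(2 * pi * phase + .q_phase[[ax]]) - qc$k2 * base_rot
    val <- .axis_baseline[[ax]] + burst_fix +
      cosang * burst_rot + sinang * qval
    if (noise_sd > 0) val <- val + rnorm(length(t), 0, noise_sd)
    out[[ax]] <- val
  }
  out
}

# Strike schedule for one leg: n_strikes heel strikes, each followed by a
# complete cycle; times snapped to the sample grid so ground-truth valley
# indices are exact.
strike_schedule <- function(n_strikes, T0, timing_jitter, lead, fs) {
  durs <- T0 * clamp(1 + timing_jitter * rnorm(n_strikes), 0.6, 1.5)
  h <- lead + c(0, cumsum(durs[-n_strikes]))
  h <- round(h * fs) / fs
  durs <- c(diff(h), round(durs[n_strikes] * fs) / fs)
  list(h = h, durs = durs)
}

#' Simulate one bilateral gait trial
#'
#' Generates left- and right-ankle tri-axial acceleration for one walking
#' trial as a quasi-periodic sequence of gait cycles. Each cycle is a sum of
#' Gaussian bursts per axis (a pronounced negative anterior-posterior burst at
#' every heel strike); the right leg runs half a cycle out of phase with the
#' left. Cycle-to-cycle variability enters as burst-amplitude jitter, a
#' variance-preserving rotation of the stance/swing waveform toward an
#' orthogonal shape (so consecutive cycles correlate at a controlled level),
#' timing scatter of the vertical loading spike, and stride-duration jitter.
#' Bilateral asymmetry enters as a persistent reshaping, rotation, and
#' loading-spike delay of the right leg. Each trial additionally draws a
#' sensor strap-mounting rotation that mixes the x/y/z channels but leaves
#' the RSS magnitude untouched. Heel-strike times are snapped to the sample
#' grid, and the true heel-strike sample indices are returned alongside the
#' signal.
#'
#' The trial always contains at least nine strides so that downstream
#' midsection-stride selection is well defined.
#'
#' @param profile A [gait_profile()].
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @param label Class label: `0` for recurrent fallers, `1` for non-fallers.
#' @param participant_id,trial_id Identifiers carried through the pipeline.
#'
#' @return A one-row tibble with columns `participant_id`, `trial_id`,
#'   `label`, `group`, `fs`, `signal` (list column: a tibble with `t_s`,
#'   `lx`, `ly`, `lz`, `rx`, `ry`, `rz` in g), and `hs_left`, `hs_right`
#'   (list columns of true heel-strike sample indices, 1-based).
#' @export
#' @examples
#' trial <- simulate_trial(nonfaller_profile(), seed = 1)
#' trial$hs_left[[1]]
simulate_trial <- function(profile, fs = 120, seed = NULL, label = 1L,
                           participant_id = "P01", trial_id = "T1") {
  validate_gait_profile(profile)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) abort("`fs` must be > 0")
  if (!label %in% c(0L, 1L)) abort("`label` must be 0 (recurrent faller) or 1 (non-faller)")

  with_local_seed(seed, {
    T0 <- profile$cycle_duration_s
    n_strikes <- max(round(profile$walk_duration_s / T0), 9L)
    lead <- round(0.6 * T0 * fs) / fs
    offset <- round((0.5 + profile$asymmetry_phase) * T0 * fs) / fs

    # schedule two spare strides per leg so end-trimming cannot leave a leg
    # short of the n_strikes it owes
    n_ext <- n_strikes + 2L
    left <- strike_schedule(n_ext, T0, profile$timing_jitter, lead, fs)
    right <- strike_schedule(n_ext, T0, profile$timing_jitter, lead + offset, fs)

    # clip both signal edges clear of heel-strike valley flanks, so neither
    # edge can present a partial (spurious) valley to the detector; the
    # right leg's previous virtual strike sits near t = 0, and the signal
    # must end away from both legs' next valleys
    t_start <- round((0.2 + profile$asymmetry_phase) * T0 * fs) / fs
    # end after both legs' n-th strike; if either leg has a valley flank at
    # the cut, move the cut forward past it (extra strides are harmless,
    # missing ones are not)
    t_end <- max(left$h[n_strikes], right$h[n_strikes]) + 0.3 * T0
    all_strikes <- sort(c(left$h, right$h))
    # asymmetric window: an included strike keeps >= 0.2 cycles of tail, an
    # excluded strike stays >= 0.14 cycles past the cut; the 0.35-cycle
    # re-placement exceeds both bounds, so alternating-leg strikes exactly
    # half a cycle apart cannot chain the cut forward indefinitely
    for (i in 1:6) {
      near <- all_strikes[all_strikes > t_end - 0.2 * T0 &
                            all_strikes <= t_end + 0.14 * T0]
      if (!length(near)) break
      t_end <- max(near) + 0.35 * T0
    }
    n_samp <- floor((t_end - t_start) * fs)
    t <- t_start + (seq_len(n_samp) - 1) / fs

    template_l <- gait_waveform_template(profile$stance_fraction)
    template_r <- template_l
    # asymmetry: alternating-sign amplitude reshaping + within-cycle time
    # shift of the right leg's post-heel-strike bursts
    sgn <- rep_len(c(1, -1), nrow(template_r))
    sgn <- sgn * ifelse(template_r$axis == "x", 0.15, 1)
    template_r$amp <- template_r$amp * (1 + profile$asymmetry_amp * sgn)
    template_r$center <- template_r$center +
      ifelse(template_r$shiftable, profile$asymmetry_phase, 0) *
      .shift_atten[match(template_r$axis, names(.shift_atten))]
    # persistent impact asymmetry: the right leg's heel-strike transients
    # are wider and its vertical loading spike arrives later, reflecting a
    # different foot-strike mechanic; this decorrelates the left-right
    # comparison without moving the x valley off the heel-strike instant
    wasym <- ifelse(template_r$axis == "x", 0.3, 1) * 0.8 * profile$asymmetry_amp
    template_r$width <- template_r$width *
      ifelse(!template_r$shiftable, 1 + wasym, 1)
    # a weaker, amplitude-asymmetric push-off also delays the contralateral
    # loading response, so the right spike's timing shifts with both
    # asymmetry parameters
    template_r$center <- template_r$center +
      ifelse(template_r$mobile,
             profile$asymmetry_phase + 0.12 * profile$asymmetry_amp, 0)

    n_cyc_ext <- n_ext + 2L
    nb <- nrow(template_l)
    # impact bursts (the heel-strike valley and its vertical counterpart,
    # the non-shiftable bumps) are stereotyped: they jitter far less than
    # the stance/swing bursts, which also keeps valleys detectable
    jit_scale <- profile$amplitude_jitter *
      ifelse(template_l$shiftable, 1, 0.3) *
      ifelse(template_l$axis == "x", 0.3, 1)
    draw_mult <- function() {
      z <- clamp(matrix(rnorm(n_cyc_ext * nb), n_cyc_ext, nb), -2.5, 2.5)
      pmax(1 + sweep(z, 2, jit_scale, "*"), 0.1)
    }
    # cycle-to-cycle impact-morphology variation: the width of the impact
    # transients varies with amplitude_jitter; a width change reshapes the
    # sharp heel-strike feature while its minimum stays at the heel-strike
    # sample
    wid_scale <- 0.6 * profile$amplitude_jitter *
      ifelse(template_l$shiftable, 0, 1) *
      ifelse(template_l$axis == "x", 0.3, 1)
    draw_wid <- function() {
      z <- clamp(matrix(rnorm(n_cyc_ext * nb), n_cyc_ext, nb), -2, 2)
      pmax(1 + sweep(z, 2, wid_scale, "*"), 0.4)
    }
    # cycle-to-cycle scatter of the vertical loading spike's timing: an
    # unstable gait does not reproduce the heel-strike-to-foot-flat
    # interval stride after stride
    draw_imp <- function() {
      clamp(rnorm(n_cyc_ext, 0, 0.35 * profile$amplitude_jitter), -0.035, 0.09)
    }
    # cycle-to-cycle drift of the within-cycle burst timing (toe-off and
    # swing events shifting relative to heel strike); scales with the
    # stride-timing variability, stays clear of the cycle boundaries
    draw_shift <- function() {
      clamp(matrix(rnorm(n_cyc_ext * nb, 0, 0.5 * profile$timing_jitter),
                   n_cyc_ext, nb), -0.12, 0.12)
    }
    # shape rotation: per-cycle random angles sized by amplitude_jitter
    # degrade stride-to-stride similarity at controlled correlation
    # cos(angle difference); the right leg carries an additional persistent
    # angle sized by asymmetry_amp, the dominant left-right shape contrast
    draw_ang <- function(base) {
      base + clamp(rnorm(n_cyc_ext, 0, 1.5 * profile$amplitude_jitter),
                   -1.2, 1.2)
    }
    mult_l <- draw_mult()
    mult_r <- draw_mult()
    shift_l <- draw_shift()
    shift_r <- draw_shift()
    wid_l <- draw_wid()
    wid_r <- draw_wid()
    imp_l <- draw_imp()
    imp_r <- draw_imp()
    ang_l <- draw_ang(0)
    ang_r <- draw_ang(2.0 * profile$asymmetry_amp)

    qcoef_l <- lapply(c(x = "x", y = "y", z = "z"), function(ax)
      orthogonal_shape(template_l, ax))
    qcoef_r <- lapply(c(x = "x", y = "y", z = "z"), function(ax)
      orthogonal_shape(template_r, ax))

    sig_l <- eval_leg_signal(t, left$h, left$durs, template_l, mult_l,
                             shift_l, wid_l, imp_l, ang_l, qcoef_l,
                             profile$noise_sd, T0)
    sig_r <- eval_leg_signal(t, right$h, right$durs, template_r, mult_r,
                             shift_r, wid_r, imp_r, ang_r, qcoef_r,
                             profile$noise_sd, T0)

    # per-trial sensor mounting rotation (x-y plane); norm-preserving, so
    # the RSS source is unaffected
    for (leg in c("l", "r")) {
      phi <- clamp(rnorm(1, 0, profile$mounting_sd), -0.85, 0.85)
      psi <- clamp(rnorm(1, 0, 0.4 * profile$mounting_sd), -0.35, 0.35)
      sig <- if (leg == "l") sig_l else sig_r
      # heading rotation (x-y), then a smaller tilt (x-z); both preserve
      # the per-sample vector norm exactly
      xn <- cos(phi) * sig$x - sin(phi) * sig$y
      yn <- sin(phi) * sig$x + cos(phi) * sig$y
      sig$y <- yn
      sig$x <- cos(psi) * xn - sin(psi) * sig$z
      sig$z <- sin(psi) * xn + cos(psi) * sig$z
      if (leg == "l") sig_l <- sig else sig_r <- sig
    }

    hs_left <- as.integer(round((left$h - t_start) * fs)) + 1L
    hs_right <- as.integer(round((right$h - t_start) * fs)) + 1L
    hs_left <- hs_left[hs_left >= 1L & hs_left <= n_samp]
    hs_right <- hs_right[hs_right >= 1L & hs_right <= n_samp]

    tibble::tibble(
      participant_id = participant_id,
      trial_id = trial_id,
      label = as.integer(label),
      group = ifelse(label == 1L, "non_faller", "recurrent_faller"),
      fs = fs,
      signal = list(tibble::tibble(
        t_s = t - t_start,
        lx = sig_l$x, ly = sig_l$y, lz = sig_l$z,
        rx = sig_r$x, ry = sig_r$y, rz = sig_r$z
      )),
      hs_left = list(hs_left),
      hs_right = list(hs_right)
    )
  })
}

# participant-level spread around the group profile; stance SDs follow the
# reported group spreads (2.2% non-fallers, 4.9% recurrent fallers), walk
# duration SDs derive from the reported 10 MWT interquartile ranges
.participant_sd <- list(
  cycle_duration_s = 0.04,
  stance_fraction = c(non_faller = 0.022, recurrent_faller = 0.049),
  jitter_sdlog = 0.15,
  walk_duration_s = c(non_faller = 0.067, recurrent_faller = 0.415)
)

draw_participant_profile <- function(group_profile, group) {
  p <- unclass(group_profile)
  p$cycle_duration_s <- clamp(
    p$cycle_duration_s + rnorm(1, 0, .participant_sd$cycle_duration_s),
    0.6, 2
  )
  p$stance_fraction <- clamp(
    p$stance_fraction + rnorm(1, 0, .participant_sd$stance_fraction[[group]]),
    0.35, 0.75
  )
  for (f in c("amplitude_jitter", "timing_jitter", "asymmetry_amp",
              "asymmetry_phase")) {
    p[[f]] <- p[[f]] * exp(rnorm(1, 0, .participant_sd$jitter_sdlog))
  }
  structure(p, class = "gait_profile")
}

#' Simulate a labeled cohort of gait trials
#'
#' Generates a full synthetic study from a [cohort_config()]: each
#' participant receives an individual gait profile drawn around their group's
#' profile (so a participant's two trials resemble each other more than two
#' participants do), and each trial draws its own 10 m walk duration around
#' the group median. All randomness flows from `config$seed`; two calls with
#' the same configuration are identical.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per trial, in the shape of
#'   [simulate_trial()] output. Zero participants yield an empty tibble.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_nonfallers = 2, n_fallers = 2, seed = 7))
#' nrow(cohort)
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config")
  with_local_seed(config$seed, {
    groups <- list(
      list(n = config$n_nonfallers, label = 1L, group = "non_faller",
           prefix = "NF", profile = config$nonfaller_profile),
      list(n = config$n_fallers, label = 0L, group = "recurrent_faller",
           prefix = "RF", profile = config$faller_profile)
    )
    rows <- list()
    for (g in groups) {
      if (g$n == 0L) next
      for (i in seq_len(g$n)) {
        pid <- sprintf("%s%02d", g$prefix, i)
        pprof <- draw_participant_profile(g$profile, g$group)
        wsd <- .participant_sd$walk_duration_s[[g$group]]
        for (j in seq_len(config$trials_per_participant)) {
          tprof <- pprof
          tprof$walk_duration_s <- max(rnorm(1, pprof$walk_duration_s, wsd), 6)
          rows[[length(rows) + 1L]] <- simulate_trial(
            tprof, fs = config$sampling_rate_hz, seed = NULL,
            label = g$label, participant_id = pid,
            trial_id = sprintf("T%d", j)
          )
        }
      }
    }
    if (length(rows) == 0L) {
      return(simulate_trial(nonfaller_profile(), seed = 1)[0, ])
    }
    dplyr::bind_rows(rows)
  })
}
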