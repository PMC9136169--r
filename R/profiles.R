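# Gait profiles and cohort configuration ---------------------------------

#' Define a gait profile for the synthetic signal generator
#'
#' A gait profile collects the kinematic and variability parameters that the
#' synthetic-cohort generator uses to emulate bilateral ankle acceleration
#' during a straight 10 m walk. Jitter parameters are coefficients of
#' variation (unitless); asymmetry parameters describe how much the right-leg
#' waveform departs from the left.
#'
#' @param cycle_duration_s Nominal stride (heel strike to ipsilateral heel
#'   strike) duration in seconds. Must be positive.
#' @param stance_fraction Fraction of the gait cycle spent in stance, strictly
#'   between 0 and 1. Shapes the placement of the toe-off burst in the
#'   waveform template.
#' @param amplitude_jitter Cycle-to-cycle waveform-variability coefficient
#'   (unitless, >= 0). Scales the per-burst amplitude jitter, the
#'   variance-preserving shape rotation of the stance/swing component, the
#'   impact-burst width jitter, and the timing scatter of the vertical
#'   loading spike; together these degrade same-side stride-to-stride
#'   similarity.
#' @param timing_jitter Cycle-to-cycle coefficient of variation of the stride
#'   duration (unitless, >= 0).
#' @param asymmetry_amp Persistent left-right waveform mismatch (unitless,
#'   >= 0). Applied as a fixed alternating-sign rescaling, a fixed shape
#'   rotation, a widened impact transient, and a delayed vertical loading
#'   spike on the right leg; a pure uniform rescaling would be invisible to
#'   the normalized cross-correlation, so the mismatch must change the
#'   waveform's shape.
#' @param asymmetry_phase Left-right timing offset beyond the nominal
#'   half-cycle, as a fraction of the cycle (>= 0). Also shifts the right
#'   leg's post-heel-strike bursts and vertical loading spike within the
#'   cycle, so it survives heel-strike re-alignment during segmentation.
#' @param noise_sd Standard deviation of additive white sensor noise, in g.
#' @param mounting_sd Standard deviation, in radians, of the per-trial
#'   strap-mounting rotation of the sensor about the vertical axis.
#'   Re-strapping a sensor never reproduces the anterior-posterior
#'   orientation exactly, so the x and y channels mix from trial to trial;
#'   the RSS magnitude is exactly invariant under this rotation, which is
#'   why the directionless source is preferred for classification.
#' @param walk_duration_s Nominal duration of one walking trial in seconds.
#'
#' @return A `gait_profile` object (named list).
#' @seealso [nonfaller_profile()], [faller_profile()], [simulate_trial()]
#' @export
#' @examples
#' gait_profile(cycle_duration_s = 1.0, walk_duration_s = 10)
gait_profile <- function(cycle_duration_s = 1.05,
                         stance_fraction = 0.574,
                         amplitude_jitter = 0.005,
                         timing_jitter = 0.006,
                         asymmetry_amp = 0.003,
                         asymmetry_phase = 0.001,
                         noise_sd = 0.01,
                         walk_duration_s = 8.43,
                         mounting_sd = 0.6) {
  p <- list(
    cycle_duration_s = cycle_duration_s,
    stance_fraction = stance_fraction,
    amplitude_jitter = amplitude_jitter,
    timing_jitter = timing_jitter,
    asymmetry_amp = asymmetry_amp,
    asymmetry_phase = asymmetry_phase,
    noise_sd = noise_sd,
    mounting_sd = mounting_sd,
    walk_duration_s = walk_duration_s
  )
  validate_gait_profile(p)
  structure(p, class = "gait_profile")
}

validate_gait_profile <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in names(p)) {
    if (!num1(p[[f]])) {
      abort(sprintf("gait profile field `%s` must be a single finite number", f))
    }
  }
  if (p$cycle_duration_s <= 0) abort("`cycle_duration_s` must be > 0")
  if (p$walk_duration_s <= 0) abort("`walk_duration_s` must be > 0")
  if (p$stance_fraction <= 0 || p$stance_fraction >= 1) {
    abort("`stance_fraction` must be strictly between 0 and 1")
  }
  for (f in c("amplitude_jitter", "timing_jitter", "asymmetry_amp",
              "asymmetry_phase", "noise_sd", "mounting_sd")) {
    if (p[[f]] < 0) abort(sprintf("`%s` must be >= 0", f))
  }
  invisible(p)
}

#' @export
print.gait_profile <- function(x, ...) {
  cat("<gait_profile>\n")
  for (f in names(x)) cat(sprintf("  %-16s %g\n", f, x[[f]]))
  invisible(x)
}

#' Default gait profiles for the two study groups
#'
#' Group-level defaults for community-dwelling older adults. Stance fractions
#' and nominal 10 m walk durations follow the clinical characteristics of the
#' two groups (non-fallers: stance 57.4% of the cycle, 10 MWT median 8.43 s;
#' recurrent fallers: 58.3%, 8.80 s). Recurrent fallers carry larger
#' cycle-to-cycle jitter and left-right asymmetry, reflecting their reduced
#' gait stability and symmetry; the magnitudes are generator choices that make
#' the two classes separable but overlapping.
#'
#' @return A `gait_profile` object.
#' @export
nonfaller_profile <- function() {
  gait_profile(
    cycle_duration_s = 1.05, stance_fraction = 0.574,
    amplitude_jitter = 0.005, timing_jitter = 0.006,
    asymmetry_amp = 0.003, asymmetry_phase = 0.001,
    noise_sd = 0.01, mounting_sd = 0.6, walk_duration_s = 8.43
  )
}

#' @rdname nonfaller_profile
#' @export
faller_profile <- function() {
  gait_profile(
    cycle_duration_s = 1.10, stance_fraction = 0.583,
    amplitude_jitter = 0.25, timing_jitter = 0.02,
    asymmetry_amp = 0.30, asymmetry_phase = 0.07,
    noise_sd = 0.01, mounting_sd = 0.6, walk_duration_s = 8.80
  )
}

#' Configure a synthetic cohort
#'
#' Describes a full synthetic study: group sizes, trials per participant,
#' sampling rate, the two group-level gait profiles, and the seed from which
#' every random draw derives. Defaults mirror the study design the pipeline
#' emulates: 15 non-fallers and 12 recurrent fallers, each walking a 10 m
#' walkway twice while wearing bilateral ankle accelerometers sampled at
#' 120 Hz.
#'
#' @param n_nonfallers,n_fallers Number of participants per group (>= 0).
#' @param trials_per_participant Number of walking trials per participant.
#' @param sampling_rate_hz Sampling rate of both ankle sensors, Hz.
#' @param nonfaller_profile,faller_profile Group-level [gait_profile()]s.
#' @param seed Integer seed; a cohort is fully reproducible from the
#'   configuration alone.
#'
#' @return A `cohort_config` object.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_nonfallers = 15,
                          n_fallers = 12,
                          trials_per_participant = 2,
                          sampling_rate_hz = 120,
                          nonfaller_profile = gaitknn::nonfaller_profile(),
                          faller_profile = gaitknn::faller_profile(),
                          seed = 1L) {
  cnt <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= 0 && x == round(x)
  if (!cnt(n_nonfallers) || !cnt(n_fallers) || !cnt(trials_per_participant)) {
    abort("participant and trial counts must be nonnegative integers")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be > 0")
  }
  validate_gait_profile(nonfaller_profile)
  validate_gait_profile(faller_profile)
  structure(
    list(
      n_nonfallers = as.integer(n_nonfallers),
      n_fallers = as.integer(n_fallers),
      trials_per_participant = as.integer(trials_per_participant),
      sampling_rate_hz = sampling_rate_hz,
      nonfaller_profile = nonfaller_profile,
      faller_profile = faller_profile,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d non-fallers + %d recurrent fallers x %d trials @ %g Hz (seed %d)\n",
              x$n_nonfallers, x$n_fallers, x$trials_per_participant,
              x$sampling_rate_hz, x$seed))
  invisible(x)
}
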