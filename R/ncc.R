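# Normalized cross-correlation gait features -----------------------------

#' Sliding-window normalized cross-correlation series
#'
#' Slides a template `alpha` (length `N`) along a record `beta` (length
#' `M >= N`) and computes, at every shift `t = 0..M-N`, the Pearson-type
#' normalized cross-correlation between `alpha` and the window
#' `beta[t+1], ..., beta[t+N]`, each centered on its own mean. Every
#' coefficient lies in `[-1, 1]`, which makes the series insensitive to the
#' absolute signal magnitude and to the scale and offset of either input.
#'
#' @param alpha Numeric template, length `N >= 2`, non-constant.
#' @param beta Numeric record, length `M >= N`.
#' @return Numeric vector of `M - N + 1` coefficients; element `i` is the
#'   coefficient at shift `t = i - 1`.
#' @details A constant (zero-variance) `beta` window has no defined
#'   correlation; its coefficient is recorded as 0 and a warning is issued,
#'   so one flat window cannot abort a cohort run. A constant `alpha` is an
#'   error.
#' @export
#' @examples
#' ncc_series(c(1, 2, 1), c(0, 1, 2, 1, 0))
ncc_series <- function(alpha, beta) {
  N <- length(alpha)
  M <- length(beta)
  if (N < 2) abort("template `alpha` must have length >= 2")
  if (M < N) abort("record `beta` must be at least as long as `alpha`")
  if (!all(is.finite(alpha)) || !all(is.finite(beta))) {
    abort("`alpha` and `beta` must be finite")
  }
  a0 <- alpha - mean(alpha)
  ssa <- sum(a0^2)
  if (ssa <= N * (1e-12 * (abs(mean(alpha)) + 1))^2) {
    abort("degenerate template: `alpha` is constant")
  }
  # rows of W are the successive beta windows, one per shift
  W <- embed(beta, N)[, N:1, drop = FALSE]
  wm <- rowMeans(W)
  ssw <- pmax(rowSums(W^2) - N * wm^2, 0)
  degen <- ssw <= N * (1e-12 * (abs(wm) + 1))^2
  num <- as.vector(W %*% a0)
  r <- numeric(M - N + 1L)
  ok <- !degen
  r[ok] <- num[ok] / sqrt(ssa * ssw[ok])
  if (any(degen)) {
    warn(sprintf("%d constant beta window(s); coefficient recorded as 0", sum(degen)))
  }
  clamp(r, -1, 1)
}

#' Build the four NCC series of one trial
#'
#' For one trial and one signal source, the record for each side is the
#' concatenation of that side's time-normalized midsection cycles, and the
#' template is one complete cycle taken from the side named by the first
#' letter of the comparison. The four combinations quantify gait stability
#' (`LL`, `RR`: template and record from the same side) and gait symmetry
#' (`LR`, `RL`: template from one side against the other side's record).
#'
#' @param left_cycles,right_cycles Numeric matrices (`n_cycles` x `L`) of
#'   time-normalized cycles, as produced by [preprocess_trial()]. Both sides
#'   must have identical dimensions.
#' @param template_index Which cycle row serves as the template. Default 3,
#'   the middle of five midsection cycles.
#' @return A tibble with columns `kind` (`"LL"`, `"RR"`, `"LR"`, `"RL"`),
#'   `t` (shift, 0-based), and `ncc`; each kind contributes
#'   `(n_cycles - 1) * L + 1` coefficients.
#' @export
build_ncc_sets <- function(left_cycles, right_cycles, template_index = 3) {
  if (!is.matrix(left_cycles) || !is.matrix(right_cycles)) {
    abort("cycle inputs must be matrices (cycles x normalized length)")
  }
  if (!identical(dim(left_cycles), dim(right_cycles))) {
    abort("left and right cycle matrices must have identical dimensions")
  }
  if (template_index < 1 || template_index > nrow(left_cycles)) {
    abort("`template_index` outside the available cycles")
  }
  beta_l <- as.vector(t(left_cycles))
  beta_r <- as.vector(t(right_cycles))
  alpha_l <- left_cycles[template_index, ]
  alpha_r <- right_cycles[template_index, ]
  series <- list(
    LL = ncc_series(alpha_l, beta_l),
    RR = ncc_series(alpha_r, beta_r),
    LR = ncc_series(alpha_l, beta_r),
    RL = ncc_series(alpha_r, beta_l)
  )
  dplyr::bind_rows(lapply(names(series), function(k) {
    tibble::tibble(kind = k, t = seq_along(series[[k]]) - 1L, ncc = series[[k]])
  }))
}

#' Mean and variability summaries of an NCC series
#'
#' `mean_feature()` is the arithmetic mean of the coefficients.
#' `variability_feature()` is the range divided by the mean,
#' `(max - min) / mean`, a unitless dispersion measure of the series.
#'
#' @param ncc Numeric vector of NCC coefficients.
#' @return A single number.
#' @export
#' @examples
#' mean_feature(c(0, 1, 0))
#' variability_feature(c(0, 1, 0))
mean_feature <- function(ncc) {
  if (length(ncc) == 0) abort("empty NCC series")
  mean(ncc)
}

#' @rdname mean_feature
#' @export
variability_feature <- function(ncc) {
  if (length(ncc) == 0) abort("empty NCC series")
  m <- mean(ncc)
  if (abs(m) < 1e-9) {
    abort("degenerate variability denominator: NCC series mean is ~0")
  }
  (max(ncc) - min(ncc)) / m
}

#' Assemble the 8-feature gait-pattern vector
#'
#' Reduces the four NCC series of one trial to the 8-feature gait-pattern
#' vector: the mean (M) and variability (V) of each series, ordered
#' `(M(RR), V(RR), M(LL), V(LL), M(RL), V(RL), M(LR), V(LR))`, followed by
#' the class label (`0` = recurrent faller, `1` = non-faller).
#'
#' @param sets Long tibble from [build_ncc_sets()] with all four kinds.
#' @param gait_label Class label, 0 or 1.
#' @param source Signal source the series were computed from.
#' @param participant_id,trial_id Identifiers.
#' @return A one-row tibble with columns `participant_id`, `trial_id`,
#'   `source`, `m_rr`, `v_rr`, `m_ll`, `v_ll`, `m_rl`, `v_rl`, `m_lr`,
#'   `v_lr`, `gait_label`.
#' @export
build_gait_pattern <- function(sets, gait_label, source = "rss",
                               participant_id = NA_character_,
                               trial_id = NA_character_) {
  kinds <- unique(sets$kind)
  if (!setequal(kinds, c("LL", "RR", "LR", "RL")) || length(kinds) != 4L) {
    abort("`sets` must contain exactly the kinds LL, RR, LR, RL")
  }
  if (!gait_label %in% c(0L, 1L)) abort("`gait_label` must be 0 or 1")
  f <- function(k, fun) fun(sets$ncc[sets$kind == k])
  tibble::tibble(
    participant_id = participant_id,
    trial_id = trial_id,
    source = source,
    m_rr = f("RR", mean_feature), v_rr = f("RR", variability_feature),
    m_ll = f("LL", mean_feature), v_ll = f("LL", variability_feature),
    m_rl = f("RL", mean_feature), v_rl = f("RL", variability_feature),
    m_lr = f("LR", mean_feature), v_lr = f("LR", variability_feature),
    gait_label = as.integer(gait_label)
  )
}

#' Names of the 8 gait-pattern feature columns, in vector order
#' @return Character vector of length 8.
#' @export
gait_feature_names <- function() {
  c("m_rr", "v_rr", "m_ll", "v_ll", "m_rl", "v_rl", "m_lr", "v_lr")
}

#' Extract gait-pattern features for a whole cohort
#'
#' Runs preprocessing and NCC feature extraction for every trial and every
#' requested signal source, yielding one gait-pattern row per (trial,
#' source). Trials that fail preprocessing (e.g. too few gait cycles) are
#' quarantined: they are dropped from the result with a warning, and the
#' reasons are attached as the `"quarantined"` attribute.
#'
#' @param cohort Cohort tibble ([simulate_cohort()] or [read_cohort()]).
#' @param sources Character vector of signal sources, subset of
#'   `c("x", "y", "z", "rss")`.
#' @param template_index,n_cycles,L,filter_order,cutoff_hz,min_separation_s,depth_sd
#'   Passed to [preprocess_trial()] and [build_ncc_sets()].
#' @return A tibble of gait-pattern rows; see [build_gait_pattern()].
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_nonfallers = 2, n_fallers = 2, seed = 3))
#' extract_gait_features(cohort, sources = "rss")
extract_gait_features <- function(cohort, sources = c("rss", "x"),
                                  template_index = 3, n_cycles = 5, L = 100,
                                  filter_order = 8, cutoff_hz = 20,
                                  min_separation_s = 0.5, depth_sd = 0.5) {
  sources <- match.arg(sources, c("x", "y", "z", "rss"), several.ok = TRUE)
  rows <- list()
  quarantined <- list()
  for (i in seq_len(nrow(cohort))) {
    trial <- cohort[i, ]
    for (src in sources) {
      res <- tryCatch(
        {
          pre <- preprocess_trial(trial, source = src, n_cycles = n_cycles,
                                  L = L, filter_order = filter_order,
                                  cutoff_hz = cutoff_hz,
                                  min_separation_s = min_separation_s,
                                  depth_sd = depth_sd)
          sets <- build_ncc_sets(pre$left, pre$right, template_index)
          build_gait_pattern(sets, trial$label[[1]], src,
                             trial$participant_id[[1]], trial$trial_id[[1]])
        },
        error = function(e) e
      )
      if (inherits(res, "error")) {
        quarantined[[length(quarantined) + 1L]] <- tibble::tibble(
          participant_id = trial$participant_id[[1]],
          trial_id = trial$trial_id[[1]], source = src,
          reason = conditionMessage(res)
        )
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    build_gait_pattern(
      tibble::tibble(kind = rep(c("LL", "RR", "LR", "RL"), each = 2),
                     t = 0:1, ncc = rep(c(0.5, 1), 4)),
      1L
    )[0, ]
  if (length(quarantined)) {
    q <- dplyr::bind_rows(quarantined)
    warn(sprintf("%d trial/source combination(s) quarantined during feature extraction", nrow(q)))
    attr(out, "quarantined") <- q
  }
  out
}
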