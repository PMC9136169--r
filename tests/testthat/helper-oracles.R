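# Independent oracles and small fixtures used across the suite.

# Direct double-loop evaluation of the normalized cross-correlation at every
# shift t = 0..M-N: each coefficient is computed from its own sums, with the
# template and window centered on their own means.
naive_ncc <- function(alpha, beta) {
  N <- length(alpha)
  M <- length(beta)
  out <- numeric(M - N + 1)
  for (t in 0:(M - N)) {
    w <- beta[(t + 1):(t + N)]
    am <- mean(alpha)
    wm <- mean(w)
    num <- 0
    da <- 0
    dw <- 0
    for (i in 1:N) {
      num <- num + (alpha[i] - am) * (w[i] - wm)
      da <- da + (alpha[i] - am)^2
      dw <- dw + (w[i] - wm)^2
    }
    out[t + 1] <- num / sqrt(da * dw)
  }
  out
}

# Exhaustive-distance kNN: compute every distance, rank by (distance, index),
# majority vote, ties to the nearest neighbor's label.
brute_knn <- function(train_x, train_y, query, k) {
  d <- sqrt(rowSums((train_x - matrix(query, nrow(train_x), ncol(train_x),
                                      byrow = TRUE))^2))
  nb <- order(d)[seq_len(k)]
  votes <- train_y[nb]
  n1 <- sum(votes == 1L)
  if (n1 * 2L == k) votes[1L] else as.integer(n1 * 2L > k)
}

# A deterministic, perfectly regular and symmetric gait profile: every cycle
# identical, left and right identical up to the half-cycle offset.
clean_profile <- function(cycle_duration_s = 1.0, walk_duration_s = 10) {
  gait_profile(
    cycle_duration_s = cycle_duration_s, stance_fraction = 0.574,
    amplitude_jitter = 0, timing_jitter = 0, asymmetry_amp = 0,
    asymmetry_phase = 0, noise_sd = 0, mounting_sd = 0,
    walk_duration_s = walk_duration_s
  )
}

# Base profile for ceteris-paribus parameter sweeps: small fixed jitters,
# no stride-duration jitter, one parameter overridden per call.
sweep_profile <- function(...) {
  args <- list(
    cycle_duration_s = 1.05, stance_fraction = 0.574,
    amplitude_jitter = 0.02, timing_jitter = 0, asymmetry_amp = 0.02,
    asymmetry_phase = 0.002, noise_sd = 0.01, mounting_sd = 0,
    walk_duration_s = 8.43
  )
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(gait_profile, args)
}

# Mean gait-pattern features over n seeded trials of one profile.
mean_features <- function(profile, seeds, source = "rss") {
  rowMeans(vapply(seeds, function(s) {
    tr <- simulate_trial(profile, seed = s)
    pre <- preprocess_trial(tr, source = source)
    f <- build_gait_pattern(build_ncc_sets(pre$left, pre$right), 1L, source)
    c(m_ll = f$m_ll, m_rr = f$m_rr, m_lr = f$m_lr, m_rl = f$m_rl)
  }, numeric(4)))
}

# Random gait-pattern feature table for classifier tests.
random_patterns <- function(n, seed, separation = 0) {
  set.seed(seed)
  label <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * 8), n, 8) + separation * label
  tbl <- tibble::as_tibble(as.data.frame(x))
  names(tbl) <- gait_feature_names()
  tbl$gait_label <- label
  tbl$participant_id <- sprintf("P%03d", seq_len(n))
  tbl$trial_id <- "T1"
  tbl$source <- "rss"
  tbl
}
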