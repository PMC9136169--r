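test_that("NCC reproduces hand-derived values and its analytic bounds", {
  # perfect self-correlation at zero shift
  a <- c(0.3, -1.2, 0.8, 2.0)
  expect_equal(ncc_series(a, a), 1)

  # worked shifts: window at t = 1 equals the template exactly, the
  # flanking windows are exactly uncorrelated with it
  expect_equal(ncc_series(c(1, 2, 1), c(0, 1, 2, 1, 0)), c(0, 1, 0))

  # perfect anticorrelation
  expect_equal(ncc_series(c(1, 2, 1), -c(1, 2, 1)), -1)

  expect_error(ncc_series(c(1), c(1, 2)), "length >= 2")
  expect_error(ncc_series(c(1, 2, 3), c(1, 2)), "as long as")
  expect_error(ncc_series(c(2, 2, 2), c(1, 2, 3, 4)), "degenerate template")
  expect_warning(r <- ncc_series(c(1, 2, 1), c(5, 5, 5, 1, 2, 1)), "constant")
  expect_equal(r[1], 0)
})

test_that("NCC is invariant to positive scale and offset of either input", {
  set.seed(10)
  for (i in 1:20) {
    alpha <- rnorm(sample(5:20, 1))
    beta <- rnorm(length(alpha) + sample(0:30, 1))
    base <- ncc_series(alpha, beta)
    a <- runif(1, 0.1, 5); b <- rnorm(1); cc <- runif(1, 0.1, 5); d <- rnorm(1)
    expect_equal(ncc_series(a * alpha + b, cc * beta + d), base,
                 tolerance = 1e-10)
  }
})

test_that("NCC coefficients always lie in [-1, 1] and match the naive oracle", {
  set.seed(11)
  for (i in 1:200) {
    N <- sample(2:20, 1)
    M <- N + sample(0:40, 1)
    alpha <- rnorm(N)
    beta <- rnorm(M)
    r <- ncc_series(alpha, beta)
    expect_length(r, M - N + 1)
    expect_true(all(r >= -1 & r <= 1))
    expect_equal(r, naive_ncc(alpha, beta), tolerance = 1e-10)
  }
})

test_that("the four comparison series have the documented structure", {
  tr <- simulate_trial(clean_profile(), seed = 2)
  pre <- preprocess_trial(tr, source = "rss")
  sets <- build_ncc_sets(pre$left, pre$right)

  expect_setequal(unique(sets$kind), c("LL", "RR", "LR", "RL"))
  expect_equal(unname(table(sets$kind))[1], 401)   # M - N + 1 = 500 - 100 + 1

  # identical cycles: every series attains 1 at the cycle-aligned shifts
  for (k in c("LL", "RR", "LR", "RL")) {
    v <- sets$ncc[sets$kind == k]
    expect_equal(v[1 + c(0, 100, 200, 300, 400)], rep(1, 5), tolerance = 1e-6)
  }
  # symmetric limit: the two cross-side series coincide
  expect_equal(sets$ncc[sets$kind == "LR"], sets$ncc[sets$kind == "RL"],
               tolerance = 1e-6)

  expect_error(build_ncc_sets(pre$left[, 1:50], pre$right), "identical dimensions")
  expect_error(build_ncc_sets(pre$left, pre$right, template_index = 9),
               "template_index")
})

test_that("asymmetry lowers cross-side peaks while same-side peaks stay perfect", {
  p <- gait_profile(cycle_duration_s = 1.0, amplitude_jitter = 0,
                    timing_jitter = 0, asymmetry_amp = 0.4,
                    asymmetry_phase = 0.05, noise_sd = 0, walk_duration_s = 10)
  pre <- preprocess_trial(simulate_trial(p, seed = 3), source = "rss")
  sets <- build_ncc_sets(pre$left, pre$right)
  expect_equal(max(sets$ncc[sets$kind == "LL"]), 1, tolerance = 1e-6)
  expect_equal(max(sets$ncc[sets$kind == "RR"]), 1, tolerance = 1e-6)
  expect_lt(max(sets$ncc[sets$kind == "LR"]), 0.995)
  expect_lt(max(sets$ncc[sets$kind == "RL"]), 0.995)
})

test_that("mean and variability features evaluate their formulas", {
  expect_equal(mean_feature(c(0, 1, 0)), 1 / 3)
  expect_equal(mean_feature(rep(1, 10)), 1)
  expect_equal(mean_feature(ncc_series(c(1, 2, 1), c(0, 1, 2, 1, 0))), 1 / 3,
               tolerance = 1e-4)

  expect_equal(variability_feature(c(0.7, 0.7, 0.7)), 0)
  expect_equal(variability_feature(c(0, 1, 0)), 3)
  expect_equal(variability_feature(c(0.5, 1.0)), 0.5 / 0.75)

  expect_error(mean_feature(numeric(0)), "empty")
  expect_error(variability_feature(c(-1, 1)), "degenerate variability")
})

test_that("the gait-pattern vector has the documented order and arity", {
  sets <- dplyr::bind_rows(lapply(c("LL", "RR", "LR", "RL"), function(k) {
    tibble::tibble(kind = k, t = 0:2, ncc = c(1, 1, 1))
  }))
  gp <- build_gait_pattern(sets, gait_label = 0L, source = "rss",
                           participant_id = "RF01", trial_id = "T1")
  expect_equal(names(gp)[4:12],
               c("m_rr", "v_rr", "m_ll", "v_ll", "m_rl", "v_rl",
                 "m_lr", "v_lr", "gait_label"))
  expect_equal(unlist(gp[gait_feature_names()]),
               setNames(rep(c(1, 0), 4), gait_feature_names()))
  expect_equal(gp$gait_label, 0L)
  expect_length(gait_feature_names(), 8)

  bad <- sets[sets$kind != "RL", ]
  expect_error(build_gait_pattern(bad, 1L), "exactly the kinds")
  expect_error(build_gait_pattern(sets, 3), "gait_label")
})

test_that("cohort feature extraction yields one labeled row per trial and source", {
  cohort <- simulate_cohort(cohort_config(n_nonfallers = 3, n_fallers = 2, seed = 9))
  feats <- extract_gait_features(cohort, sources = c("rss", "x"))
  expect_equal(nrow(feats), 20)
  expect_equal(sum(feats$gait_label == 0), 8)
  expect_true(all(abs(feats[, c("m_rr", "m_ll", "m_rl", "m_lr")]) <= 1))
  expect_true(all(is.finite(as.matrix(feats[, gait_feature_names()]))))

  # round-trip through the CSV interchange
  path <- withr::local_tempfile(fileext = ".csv")
  write_gait_features(feats, path)
  back <- read_gait_features(path)
  expect_equal(as.data.frame(back), as.data.frame(feats),
               tolerance = 1e-12, ignore_attr = TRUE)
})
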