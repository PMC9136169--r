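test_that("kNN votes among the nearest training vectors", {
  train <- random_patterns(10, seed = 1)
  # a query equal to a training vector returns that vector's label at k = 1
  for (i in c(1, 4, 7)) {
    q <- as.numeric(train[i, gait_feature_names()])
    expect_equal(knn_classify(train, q, k = 1), train$gait_label[i])
  }

  # k = 3 majority among hand-placed neighbors labeled {0, 0, 1}
  tbl <- random_patterns(3, seed = 2)
  tbl[, gait_feature_names()] <- 0
  tbl[1, "m_rr"] <- 0.1; tbl[2, "m_rr"] <- 0.2; tbl[3, "m_rr"] <- 0.3
  tbl$gait_label <- c(0L, 0L, 1L)
  expect_equal(knn_classify(tbl, rep(0, 8), k = 3), 0L)

  expect_error(knn_classify(train[0, ], rep(0, 8), 1), "empty")
  expect_error(knn_classify(train, rep(0, 8), 11), "between 1")
})

test_that("kNN agrees with the exhaustive-distance oracle and with class::knn", {
  set.seed(20)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    train <- random_patterns(n, seed = rep)
    queries <- matrix(rnorm(5 * 8), 5, 8)
    k <- sample(c(1, 3, 5), 1)
    got <- knn_classify(train, queries, k)
    x <- as.matrix(train[, gait_feature_names()])
    want <- vapply(1:5, function(i) brute_knn(x, train$gait_label, queries[i, ], k),
                   integer(1))
    expect_equal(got, want)
    # continuous features make distance ties impossible, so the standard
    # implementation must agree as well
    ref <- as.integer(as.character(
      class::knn(x, queries, factor(train$gait_label), k = k)
    ))
    expect_equal(got, ref)
  }
})

test_that("stratified cross-validation is seeded, balanced, and leak-free", {
  pat <- random_patterns(40, seed = 3, separation = 6)
  cv <- cross_validate(pat, k = 3, n_folds = 5, seed = 1)

  # perfectly separated clusters classify perfectly
  expect_equal(cv$metrics$accuracy, 1)
  expect_equal(cv$metrics$mcc, 1)

  # per-class fold sizes differ by at most one
  tab <- table(cv$predictions$fold, cv$predictions$truth)
  expect_lte(max(tab[, 1]) - min(tab[, 1]), 1)
  expect_lte(max(tab[, 2]) - min(tab[, 2]), 1)

  # every vector predicted exactly once; same seed, same folds
  expect_equal(nrow(cv$predictions), 40)
  cv2 <- cross_validate(pat, k = 3, n_folds = 5, seed = 1)
  expect_identical(cv$predictions, cv2$predictions)

  expect_error(cross_validate(pat, k = 3, n_folds = 1), "n_folds")
  expect_error(cross_validate(random_patterns(6, 1), k = 3, n_folds = 5),
               "fewer than")
})

test_that("grouped cross-validation keeps a participant's trials in one fold", {
  pat <- random_patterns(40, seed = 8, separation = 4)
  pat$participant_id <- rep(sprintf("P%02d", 1:20), each = 2)
  cv <- cross_validate(pat, k = 3, n_folds = 5, seed = 2,
                       group_by_participant = TRUE)
  folds_per_participant <- tapply(cv$predictions$fold,
                                  cv$predictions$participant_id,
                                  function(f) length(unique(f)))
  expect_true(all(folds_per_participant == 1))
})

test_that("label-shuffled features classify at chance level", {
  for (s in 1:20) {
    pat <- random_patterns(200, seed = 1000 + s)  # labels independent of features
    cv <- cross_validate(pat, k = 3, n_folds = 5, seed = s)
    expect_gte(cv$metrics$accuracy, 0.35)
    expect_lte(cv$metrics$accuracy, 0.65)
  }
})

test_that("K selection minimizes the cross-validated error with ties toward smaller K", {
  pat <- random_patterns(40, seed = 5, separation = 6)
  expect_equal(select_k(pat, candidates = 3, seed = 1)$k_best, 3)

  # separable data: every candidate errs 0, tie broken toward 3
  sel <- select_k(pat, candidates = c(3, 5, 7), seed = 1)
  expect_equal(sel$k_best, 3)
  expect_equal(sel$curve$error, rep(0, 3))

  # the curve agrees with independently recomputed error rates
  pat2 <- random_patterns(60, seed = 6, separation = 1)
  sel2 <- select_k(pat2, candidates = c(3, 5, 7, 9), seed = 2)
  for (i in seq_len(nrow(sel2$curve))) {
    cv <- cross_validate(pat2, k = sel2$curve$k[i], n_folds = 5, seed = 2)
    expect_equal(sel2$curve$error[i], 1 - cv$metrics$accuracy)
  }
  expect_equal(sel2$k_best,
               sel2$curve$k[order(sel2$curve$error, sel2$curve$k)][1])

  expect_warning(sel3 <- select_k(pat, candidates = c(3, 200), seed = 1), "dropped")
  expect_error(select_k(pat, candidates = 500, seed = 1), "no candidate")
})

test_that("fit_fall_knn with k = 'auto' attaches the selection curve", {
  pat <- random_patterns(50, seed = 7, separation = 2)
  fit <- fit_fall_knn(pat, k = "auto", candidates = c(3, 5, 7), seed = 4)
  expect_s3_class(fit, "fall_knn_cv")
  expect_equal(nrow(fit$k_curve), 3)
  expect_true(fit$k %in% c(3, 5, 7))
  g <- glance(fit)
  expect_equal(g$n, 50)
  expect_equal(g$k, fit$k)
  td <- tidy(fit)
  expect_setequal(unique(td$class), c("non_faller", "recurrent_faller"))
  expect_setequal(unique(td$metric),
                  c("sensitivity", "specificity", "precision", "recall", "f1"))
})
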