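# k-nearest-neighbor classification of gait patterns ---------------------

as_feature_matrix <- function(features) {
  cols <- gait_feature_names()
  missing <- setdiff(cols, names(features))
  if (length(missing)) {
    abort(paste0("feature table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(features[, cols])
  if (!all(is.finite(m))) abort("gait-pattern features must be finite")
  m
}

#' Classify query vectors with deterministic k-nearest neighbors
#'
#' Assigns each query the majority label among its `k` nearest training
#' vectors under Euclidean distance over the 8 gait-pattern features.
#' Determinism: neighbors are ranked by `(distance, training index)`, so
#' equidistant neighbors at the k-th radius resolve to the earliest training
#' row; a tied vote (possible only for even `k` in the two-class setting)
#' resolves to the class of the single nearest neighbor.
#'
#' @param train Feature tibble with the 8 feature columns (see
#'   [gait_feature_names()]) and `gait_label`.
#' @param query Feature tibble, a numeric matrix with 8 columns, or a single
#'   8-vector.
#' @param k Number of neighbors, `1 <= k <= nrow(train)`.
#' @return Integer vector of predicted labels, one per query row.
#' @export
knn_classify <- function(train, query, k) {
  if (nrow(train) == 0) abort("empty training set")
  if (k < 1 || k > nrow(train)) {
    abort(sprintf("`k` must be between 1 and the training size (%d)", nrow(train)))
  }
  train_x <- as_feature_matrix(train)
  train_y <- train$gait_label
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  query_x <- if (is.data.frame(query)) as_feature_matrix(query) else query
  if (ncol(query_x) != ncol(train_x)) abort("query and training dimensions differ")
  vapply(seq_len(nrow(query_x)), function(i) {
    d <- sqrt(colSums((t(train_x) - query_x[i, ])^2))
    nb <- order(d)[seq_len(k)]           # stable: ties fall to earlier rows
    votes <- train_y[nb]
    n1 <- sum(votes == 1L)
    if (n1 * 2L == k) votes[1L] else as.integer(n1 * 2L > k)
  }, integer(1))
}

# stratified fold assignment: within each class, shuffle then deal into
# folds round-robin, so per-class fold sizes differ by at most one
stratified_folds <- function(labels, n_folds, seed, groups = NULL) {
  with_local_seed(seed, {
    fold <- integer(length(labels))
    if (is.null(groups)) {
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        if (length(idx) < n_folds) {
          abort(sprintf("class %s has %d member(s), fewer than %d folds",
                        cls, length(idx), n_folds))
        }
        fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      # keep all rows of one participant in one fold, stratified by class
      gtab <- unique(data.frame(group = groups, label = labels))
      gfold <- integer(nrow(gtab))
      for (cls in unique(gtab$label)) {
        gidx <- which(gtab$label == cls)
        if (length(gidx) < n_folds) {
          abort(sprintf("class %s has %d participant(s), fewer than %d folds",
                        cls, length(gidx), n_folds))
        }
        gfold[sample(gidx)] <- rep_len(seq_len(n_folds), length(gidx))
      }
      fold <- gfold[match(groups, gtab$group)]
    }
    fold
  })
}

#' Cross-validated kNN classification of gait patterns
#'
#' Splits the gait-pattern vectors into seeded, stratified folds, predicts
#' each vector exactly once with a kNN model trained on the remaining folds,
#' and aggregates the out-of-fold predictions into a confusion matrix and
#' the full metric panel.
#'
#' @param features Gait-pattern tibble from [extract_gait_features()] (one
#'   source at a time).
#' @param k Number of neighbors.
#' @param n_folds Number of folds. Default 5.
#' @param seed Integer seed for the fold assignment.
#' @param group_by_participant If `TRUE`, all trials of one participant stay
#'   in the same fold, preventing within-participant leakage between
#'   training and test folds. Default `FALSE`, which pools all trial
#'   vectors before splitting.
#' @param scale_features If `TRUE`, features are z-scored using the training
#'   folds' means and SDs within each split. Default `FALSE`.
#' @return A `fall_knn_cv` object: confusion matrix, metric panel, fold
#'   assignments, and per-vector predictions. Supports [tidy()],
#'   [glance()], and [autoplot()].
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_nonfallers = 6, n_fallers = 6, seed = 2))
#' feats <- extract_gait_features(cohort, sources = "rss")
#' glance(cross_validate(feats, k = 3, seed = 1))
cross_validate <- function(features, k, n_folds = 5, seed = 1L,
                           group_by_participant = FALSE,
                           scale_features = FALSE) {
  if (n_folds < 2) abort("`n_folds` must be >= 2")
  if (length(unique(features$source)) > 1) {
    abort("`features` mixes sources; cross-validate one source at a time")
  }
  labels <- features$gait_label
  groups <- if (group_by_participant) features$participant_id else NULL
  fold <- stratified_folds(labels, n_folds, seed, groups)
  x <- as_feature_matrix(features)
  pred <- integer(nrow(features))
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (!length(te)) next
    if (k > length(tr)) {
      abort(sprintf("k = %d exceeds the training size (%d) of fold %d", k, length(tr), f))
    }
    tr_x <- x[tr, , drop = FALSE]
    te_x <- x[te, , drop = FALSE]
    if (scale_features) {
      mu <- colMeans(tr_x)
      sdv <- apply(tr_x, 2, sd)
      sdv[sdv == 0] <- 1
      tr_x <- sweep(sweep(tr_x, 2, mu), 2, sdv, "/")
      te_x <- sweep(sweep(te_x, 2, mu), 2, sdv, "/")
    }
    tr_tbl <- tibble::as_tibble(as.data.frame(tr_x))
    names(tr_tbl) <- gait_feature_names()
    tr_tbl$gait_label <- labels[tr]
    pred[te] <- knn_classify(tr_tbl, te_x, k)
  }
  cm <- confusion_matrix(labels, pred)
  metrics <- classification_metrics(cm)
  structure(
    list(
      k = k, n_folds = n_folds, seed = seed,
      source = if (nrow(features)) features$source[[1]] else NA_character_,
      group_by_participant = group_by_participant,
      confusion = cm, metrics = metrics,
      predictions = tibble::tibble(
        participant_id = features$participant_id,
        trial_id = features$trial_id,
        fold = fold, truth = labels, pred = pred
      )
    ),
    class = "fall_knn_cv"
  )
}

#' @export
print.fall_knn_cv <- function(x, ...) {
  cat(sprintf("<fall_knn_cv> k = %d, %d-fold CV, source = %s\n",
              x$k, x$n_folds, x$source))
  cat(sprintf("  accuracy %.3f, MCC %.3f\n", x$metrics$accuracy, x$metrics$mcc))
  invisible(x)
}

#' Select the neighborhood size K by cross-validated error rate
#'
#' Evaluates each candidate K with the same seeded fold assignment and
#' returns the candidate with the lowest cross-validated error rate, ties
#' broken toward smaller K (a smaller neighborhood is cheaper and no worse).
#' K = 1 is excluded from the default grid because the single nearest
#' neighbor overfits. Candidates larger than the smallest training split are
#' dropped with a warning.
#'
#' @inheritParams cross_validate
#' @param candidates Integer vector of K values to try. Default
#'   `c(3, 5, 7, 9, 11)`.
#' @return A list: `k_best`, and `curve` (tibble of `k`, `error`,
#'   `accuracy`).
#' @export
select_k <- function(features, candidates = c(3, 5, 7, 9, 11), n_folds = 5,
                     seed = 1L, group_by_participant = FALSE,
                     scale_features = FALSE) {
  if (!length(candidates)) abort("`candidates` must be nonempty")
  min_train <- nrow(features) - ceiling(nrow(features) / n_folds)
  valid <- candidates[candidates >= 1 & candidates <= min_train]
  if (!length(valid)) abort("no candidate K fits the training splits")
  if (length(valid) < length(candidates)) {
    warn("dropped candidate K value(s) larger than the training splits")
  }
  curve <- purrr::map_dfr(valid, function(k) {
    cv <- cross_validate(features, k, n_folds, seed,
                         group_by_participant, scale_features)
    tibble::tibble(k = k, accuracy = cv$metrics$accuracy,
                   error = 1 - cv$metrics$accuracy)
  })
  best <- curve$k[order(curve$error, curve$k)][1]
  list(k_best = best, curve = curve)
}

#' Fit the full kNN fall-risk classifier for one signal source
#'
#' Convenience wrapper: optionally selects K by cross-validated error rate
#' ([select_k()]), then runs the final cross-validation at the chosen K.
#'
#' @inheritParams cross_validate
#' @param k Either a fixed integer K or `"auto"` to select from
#'   `candidates`.
#' @param candidates Candidate grid used when `k = "auto"`.
#' @return A `fall_knn_cv` object, with the K-selection `curve` attached
#'   when `k = "auto"`.
#' @export
fit_fall_knn <- function(features, k = "auto", candidates = c(3, 5, 7, 9, 11),
                         n_folds = 5, seed = 1L,
                         group_by_participant = FALSE,
                         scale_features = FALSE) {
  curve <- NULL
  if (identical(k, "auto")) {
    sel <- select_k(features, candidates, n_folds, seed,
                    group_by_participant, scale_features)
    k <- sel$k_best
    curve <- sel$curve
  }
  fit <- cross_validate(features, k, n_folds, seed,
                        group_by_participant, scale_features)
  fit$k_curve <- curve
  fit
}
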