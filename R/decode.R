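#' Condition pair for two-class decoding
#'
#' @param target condition id scored as the positive class.
#' @param control condition id of the other class; must differ from
#'   `target`.
#' @return an object of class `condition_pair`.
#' @export
condition_pair <- function(target, control) {
  if (identical(target, control)) stop_eegmvpa("`target` must differ from `control`.")
  structure(list(target = as.character(target), control = as.character(control)),
            class = "condition_pair")
}

#' @export
format.condition_pair <- function(x, ...) paste0(x$target, " vs ", x$control)

#' @export
print.condition_pair <- function(x, ...) {
  cat("<condition_pair>", format(x), "\n"); invisible(x)
}

#' Train-set z-scoring applied to held-out data
#'
#' Per feature (column): subtract the training mean and divide by the
#' training standard deviation, applying the *same* transform to the test
#' set so no test information leaks into the normalisation. Features with
#' zero training variance are flagged and passed through with unit scale
#' (they become all-zero after centring).
#'
#' @param train,test numeric matrices `[samples x features]` with matching
#'   feature count.
#' @return list with `train`, `test` (transformed matrices) and `flagged`
#'   (indices of zero-variance features).
#' @export
zscore_train_apply <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, sd)
  flagged <- which(sdv == 0 | !is.finite(sdv))
  sdv[flagged] <- 1
  list(
    train = sweep(sweep(train, 2L, mu), 2L, sdv, "/"),
    test = sweep(sweep(test, 2L, mu), 2L, sdv, "/"),
    flagged = flagged
  )
}

#' Two-class linear discriminant with shrinkage covariance
#'
#' Fits LDA from the class means and the pooled within-class covariance
#' `S`, regularised toward a scaled identity:
#' `S_shrunk = (1 - lambda) S + lambda (tr(S)/p) I`. The discriminant is
#' `w = S_shrunk^{-1} (mu1 - mu0)`, `b = -w . (mu1 + mu0)/2` (equal
#' priors), and a sample is assigned the target class iff `w . x + b > 0`;
#' an exact tie goes to the control class. With `lambda = NULL` the
#' analytic Ledoit-Wolf intensity is estimated from the training data —
#' the default, since ~63 channels against a few hundred trials makes the
#' raw covariance ill-conditioned.
#'
#' @param x numeric matrix `[samples x features]`.
#' @param y logical or 0/1 vector; `TRUE`/1 marks the target class.
#' @param lambda shrinkage intensity in `[0, 1]`, or `NULL` for the
#'   Ledoit-Wolf estimate.
#' @return an object of class `lda_model` with elements `w`, `b`,
#'   `lambda`, `mu1`, `mu0`, `cov`, `cov_shrunk`.
#' @export
lda_shrink <- function(x, y, lambda = NULL) {
  x <- as.matrix(x)
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stop_eegmvpa("Both classes must be present.")
  if (any(!is.finite(x))) stop_eegmvpa("`x` contains non-finite values.")
  fit <- lda_fit_cpp(x, y, if (is.null(lambda)) -1 else lambda)
  structure(c(fit, list(p = ncol(x), n = nrow(x))), class = "lda_model")
}

#' @param object an `lda_model`.
#' @param newdata matrix of samples to classify.
#' @param ... unused.
#' @rdname lda_shrink
#' @export
predict.lda_model <- function(object, newdata, ...) {
  score <- as.matrix(newdata) %*% object$w + object$b
  as.integer(score > 0)
}

#' @exportS3Method generics::glance
glance.lda_model <- function(x, ...) {
  tibble(lambda = x$lambda, n = x$n, p = x$p,
         w_norm = sqrt(sum(x$w^2)), b = x$b)
}

#' Balanced, seeded k-fold assignment
#'
#' Truncates both classes to a common size divisible by `k` (random
#' subsample) and deals each class's trials evenly across the `k` folds, so
#' every fold holds the same number of trials of each class. Deterministic
#' given `seed`.
#'
#' @param labels per-trial labels (two classes).
#' @param k fold count; each class must have at least `k` trials.
#' @param seed integer seed.
#' @return integer vector over trials: fold id `1..k`, `0` for trials
#'   dropped by balancing.
#' @export
make_balanced_folds <- function(labels, k, seed) {
  classes <- unique(labels)
  if (length(classes) != 2L) stop_eegmvpa("Exactly two classes expected.")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < k)) {
    stop_eegmvpa(sprintf("Each class needs >= k = %d trials (have %s).",
                         k, paste(counts, collapse = ", ")))
  }
  m <- (min(counts) %/% k) * k
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl), m)
      fold[idx] <- rep(seq_len(k), each = m / k)
    }
  })
  fold
}

#' Per-timepoint cross-validated decoding timecourse
#'
#' For every repetition (a fresh balanced fold assignment derived from
#' `seed`) and every timepoint, the scalp-channel pattern at that timepoint
#' is decoded with shrinkage LDA under leave-one-fold-out cross-validation:
#' z-scoring and fitting use only the training folds; accuracy is the mean
#' over held-out folds. Chance level is 0.5.
#'
#' @param ds an [eeg_epochs()], already cropped to the analysis window.
#' @param pair a [condition_pair()].
#' @param k fold count.
#' @param n_repetitions number of fold-assignment repetitions.
#' @param lambda shrinkage intensity or `NULL` (Ledoit-Wolf).
#' @param seed master seed; repetition `r` uses a derived sub-seed.
#' @return a `decoding_timecourse`: accuracy matrix
#'   `[n_repetitions x n_times]`, times, pair, fold bookkeeping.
#' @export
decode_timecourse <- function(ds, pair, k = 10L, n_repetitions = 20L,
                              lambda = NULL, seed = 1L) {
  stopifnot(inherits(pair, "condition_pair"))
  sub <- select_conditions(ds, c(pair$target, pair$control))
  feats <- sub$data[, scalp_channels(sub), , drop = FALSE]
  y1 <- as.integer(sub$labels == pair$target)
  lam <- if (is.null(lambda)) -1 else lambda
  acc <- matrix(NA_real_, n_repetitions, n_times(sub))
  folds <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    fold <- make_balanced_folds(sub$labels, k, derive_seed(seed, 301L, r))
    folds[[r]] <- fold
    acc[r, ] <- as.vector(decode_cv_cpp(feats, y1, fold, lam))
  }
  new_decoding_timecourse(acc, sub$times, pair, k = k, seed = seed,
                          folds = folds, kind = "cv",
                          subject_id = ds$subject_id)
}

new_decoding_timecourse <- function(acc, times, pair, k, seed, folds,
                                    kind, subject_id = NA_character_,
                                    test_condition = NA_character_) {
  structure(list(
    accuracies = acc, times = times, pair = pair, k = k, chance = 0.5,
    seed = seed, fold_assignments = folds, kind = kind,
    subject_id = subject_id, test_condition = test_condition
  ), class = "decoding_timecourse")
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf("<decoding_timecourse> %s%s: %d reps x %d timepoints, peak %.3f\n",
              format(x$pair),
              if (!is.na(x$test_condition)) paste0(" -> ", x$test_condition) else "",
              nrow(x$accuracies), ncol(x$accuracies),
              max(colMeans(x$accuracies))))
  invisible(x)
}

# balanced subsample (equal class counts) of train-pair trials for the
# cross-classification repetitions
balance_subsample <- function(labels, pair, seed) {
  i1 <- which(labels == pair$target)
  i0 <- which(labels == pair$control)
  m <- min(length(i1), length(i0))
  with_seed(seed, {
    sort(c(sample(i1, m), sample(i0, m)))
  })
}

#' Cross-classification timecourse
#'
#' Per timepoint, a shrinkage-LDA classifier is trained on *all* balanced
#' train-pair trials (z-scored on that training set) and applied to the
#' trials of a third, held-out condition; the score is the fraction of
#' test-condition trials classified as the train target. 0.5 means no bias
#' toward either trained class. Each repetition redraws the balancing
#' subsample.
#'
#' @inheritParams decode_timecourse
#' @param train_pair a [condition_pair()] to train on.
#' @param test_condition condition id to test on; must not be in
#'   `train_pair`.
#' @return a `decoding_timecourse` with `kind = "cross"`.
#' @export
cross_classify_timecourse <- function(ds, train_pair, test_condition,
                                      n_repetitions = 20L, lambda = NULL,
                                      seed = 1L) {
  stopifnot(inherits(train_pair, "condition_pair"))
  if (test_condition %in% c(train_pair$target, train_pair$control)) {
    stop_eegmvpa("`test_condition` must not be part of `train_pair`.")
  }
  res <- cross_decode_engine(ds, train_pair, test_condition, n_repetitions,
                             lambda, seed, tg = FALSE)
  new_decoding_timecourse(res$acc, res$times, train_pair, k = NA_integer_,
                          seed = seed, folds = res$subsamples,
                          kind = "cross", subject_id = ds$subject_id,
                          test_condition = test_condition)
}

cross_decode_engine <- function(ds, train_pair, test_condition,
                                n_repetitions, lambda, seed, tg) {
  train_ds <- select_conditions(ds, c(train_pair$target, train_pair$control))
  test_ds <- select_conditions(ds, test_condition)
  if (n_trials(test_ds) == 0L) stop_eegmvpa("Test condition has no trials.")
  scalp <- scalp_channels(ds)
  test_feats <- test_ds$data[, scalp, , drop = FALSE]
  lam <- if (is.null(lambda)) -1 else lambda
  nt <- n_times(ds)
  acc <- if (tg) array(NA_real_, c(n_repetitions, nt, nt)) else
    matrix(NA_real_, n_repetitions, nt)
  subsamples <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    idx <- balance_subsample(train_ds$labels, train_pair,
                             derive_seed(seed, 401L, r))
    subsamples[[r]] <- idx
    feats <- train_ds$data[idx, scalp, , drop = FALSE]
    y1 <- as.integer(train_ds$labels[idx] == train_pair$target)
    out <- cross_decode_cpp(feats, y1, test_feats, lam, tg)
    if (tg) acc[r, , ] <- out else acc[r, ] <- out[, 1]
  }
  list(acc = acc, times = ds$times, subsamples = subsamples)
}

#' Temporal generalization matrix
#'
#' Extends [cross_classify_timecourse()] across time: the classifier fit at
#' train time `t` is applied to the held-out condition's features at every
#' test time `t'`, yielding a train-time x test-time score matrix. Test
#' features at `t'` are standardised with the *training-pair* statistics
#' computed at `t'`, so only the classifier — not the scaler — crosses
#' time. The diagonal equals the matched-time cross-classification
#' timecourse exactly under a shared seed.
#'
#' @inheritParams cross_classify_timecourse
#' @return a `tg_matrix`: `values` is the repetition-averaged
#'   `[n_train_times x n_test_times]` score matrix; `per_rep` keeps the
#'   repetition-resolved array.
#' @export
temporal_generalization <- function(ds, train_pair, test_condition,
                                    n_repetitions = 20L, lambda = NULL,
                                    seed = 1L) {
  stopifnot(inherits(train_pair, "condition_pair"))
  if (test_condition %in% c(train_pair$target, train_pair$control)) {
    stop_eegmvpa("`test_condition` must not be part of `train_pair`.")
  }
  res <- cross_decode_engine(ds, train_pair, test_condition, n_repetitions,
                             lambda, seed, tg = TRUE)
  values <- apply(res$acc, c(2, 3), mean)
  structure(list(
    values = values, per_rep = res$acc, times = res$times,
    train_pair = train_pair, test_condition = test_condition,
    seed = seed, subject_id = ds$subject_id
  ), class = "tg_matrix")
}

#' @export
print.tg_matrix <- function(x, ...) {
  cat(sprintf("<tg_matrix> train %s, test %s: %d x %d times, diag peak %.3f\n",
              format(x$train_pair), x$test_condition,
              nrow(x$values), ncol(x$values), max(diag(x$values))))
  invisible(x)
}
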