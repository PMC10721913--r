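test_that("train-set z-scoring normalises train and never peeks at test", {
  set.seed(2)
  tr <- matrix(rnorm(40, mean = 3, sd = 2), 10, 4)
  te <- matrix(rnorm(20, mean = 3, sd = 2), 5, 4)
  zs <- zscore_train_apply(tr, te)
  expect_lt(max(abs(colMeans(zs$train))), 1e-10)
  expect_equal(apply(zs$train, 2, sd), rep(1, 4), tolerance = 1e-10)
  # brute-force per-feature formula on the test block
  mu <- colMeans(tr); sdv <- apply(tr, 2, sd)
  expect_equal(zs$test, sweep(sweep(te, 2, mu), 2, sdv, "/"))
  # train used as its own test
  self <- zscore_train_apply(tr, tr)
  expect_lt(max(abs(colMeans(self$test))), 1e-10)
  # constant feature flagged and passed through as zeros
  tr2 <- cbind(tr, 5)
  zs2 <- zscore_train_apply(tr2, cbind(te, 5))
  expect_equal(zs2$flagged, 5L, ignore_attr = TRUE)
  expect_true(all(zs2$train[, 5] == 0) && all(zs2$test[, 5] == 0))
})

test_that("shrinkage LDA recovers closed-form solutions", {
  # 1-D, equal class variances: boundary at the midpoint of the means
  x1 <- matrix(c(-2, -1, 0, 2, 3, 4), ncol = 1) # means 1 apart... m0=-1, m1=3
  y1 <- c(0, 0, 0, 1, 1, 1)
  fit <- lda_shrink(x1, y1, lambda = 0)
  boundary <- -fit$b / fit$w
  expect_equal(as.numeric(boundary), 1) # (m0 + m1) / 2
  expect_equal(predict(fit, matrix(c(0.9, 1.1), ncol = 1)), c(0L, 1L))
  # 2-D, identity-like covariance, means (0,0) and (2,0): w prop (2,0),
  # boundary x1 = 1
  x2 <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
              c(1, 0), c(3, 0), c(2, -1), c(2, 1))
  y2 <- rep(0:1, each = 4)
  fit2 <- lda_shrink(x2, y2, lambda = 0)
  expect_equal(fit2$w[2], 0)
  expect_gt(fit2$w[1], 0)
  expect_equal(-fit2$b / fit2$w[1], 1)
  expect_error(lda_shrink(x2, rep(1, 8)), "Both classes")
})

test_that("LDA predictions equal a brute-force discriminant over 50 seeds", {
  for (seed in 1:50) {
    set.seed(seed)
    x <- matrix(rnorm(40 * 6), 40, 6)
    y <- rep(0:1, each = 20)
    x[y == 1, ] <- x[y == 1, ] + rnorm(6) / 2
    newdata <- matrix(rnorm(15 * 6), 15, 6)
    fit <- lda_shrink(x, y, lambda = 0.1)
    expect_identical(predict(fit, newdata),
                     lda_oracle_predict(x, y, 0.1, newdata))
  }
})

test_that("LDA with no shrinkage agrees with an established implementation", {
  set.seed(33)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(0:1, 30)
  x[y == 1, ] <- x[y == 1, ] + c(0.8, -0.4, 0.2, 0)
  newdata <- matrix(rnorm(40 * 4), 40, 4)
  ours <- predict(lda_shrink(x, y, lambda = 0), newdata)
  mass <- as.integer(as.character(
    predict(MASS::lda(x, grouping = y), newdata)$class))
  expect_equal(mean(ours == mass), 1)
})

test_that("balanced folds hold equal class counts and are seeded", {
  labels <- rep(c("hands", "animals"), each = 128)
  fold <- make_balanced_folds(labels, k = 10, seed = 3)
  expect_equal(sum(fold > 0), 240) # 120 + 120 used
  for (f in 1:10) {
    expect_equal(sum(fold == f & labels == "hands"), 12)
    expect_equal(sum(fold == f & labels == "animals"), 12)
  }
  expect_identical(fold, make_balanced_folds(labels, k = 10, seed = 3))
  expect_false(identical(fold, make_balanced_folds(labels, k = 10, seed = 4)))
  # k = class count -> leave-one-per-class-out
  lab2 <- rep(c("a", "b"), each = 5)
  f2 <- make_balanced_folds(lab2, k = 5, seed = 1)
  for (f in 1:5) expect_equal(sum(f2 == f), 2)
  expect_error(make_balanced_folds(lab2, k = 6, seed = 1), ">= k")
})

test_that("null-label decoding sits at chance", {
  accs <- vapply(1:50, function(seed) {
    s <- quick_sim(seed, n_trials = 20, n_ch = 5, sfreq = 30,
                   window = c(0, 200))
    tc <- decode_timecourse(s$epochs, condition_pair("a", "b"), k = 4,
                            n_repetitions = 1, seed = seed)
    mean(tc$accuracies)
  }, numeric(1))
  # grand mean over seeds and timepoints within 3 binomial SEs of chance
  n_eff <- 50 * 6 * 20 # seeds x timepoints x test trials
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / n_eff) + 0.01)
})

test_that("a strong effect is decoded inside its window only", {
  ef <- effect_spec("a", c(100, 300), amplitude = 8, topography_seed = 2)
  s <- quick_sim(4, n_trials = 40, n_ch = 8, sfreq = 50,
                 window = c(-100, 400), effects = list(ef), jitter = 0)
  tc <- decode_timecourse(s$epochs, condition_pair("a", "b"), k = 5,
                          n_repetitions = 2, seed = 6)
  m <- colMeans(tc$accuracies)
  inside <- tc$times >= 100 & tc$times < 300
  expect_gt(min(m[inside]), 0.9)
  expect_lt(max(abs(m[!inside] - 0.5)), 0.2)
  # determinism given (seed, data)
  tc2 <- decode_timecourse(s$epochs, condition_pair("a", "b"), k = 5,
                           n_repetitions = 2, seed = 6)
  expect_identical(tc$accuracies, tc2$accuracies)
})

test_that("accuracy under label permutation is centred on 0.5", {
  s <- quick_sim(8, n_trials = 64, n_ch = 6, sfreq = 10, window = c(0, 100))
  ds <- s$epochs
  feats <- ds$data[, scalp_channels(ds), 1, drop = FALSE] # one timepoint
  n <- n_trials(ds)
  Y1 <- matrix(0L, n, 100)
  FOLD <- matrix(0L, n, 100)
  for (i in 1:100) {
    yp <- withr::with_seed(i, sample(ds$labels))
    Y1[, i] <- as.integer(yp == "a")
    FOLD[, i] <- make_balanced_folds(yp, 4, seed = 1000 + i)
  }
  acc <- eegmvpa:::decode_cv_batch_cpp(feats, Y1, FOLD, -1)
  expect_lt(abs(mean(acc) - 0.5), 0.01)
})

test_that("cross-classification scores are leak-free and match an R oracle", {
  ef <- effect_spec(c("a", "b"), c(50, 150), amplitude = 3, topography_seed = 5)
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 16,
                    conditions = c("a", "b", "c"), n_scalp_channels = 5,
                    sfreq = 40, epoch_window = c(-100, 200),
                    effects = list(ef), seed = 12)
  ds <- simulate_subject(cfg, 1)$epochs
  ct <- cross_classify_timecourse(ds, condition_pair("a", "b"), "c",
                                  n_repetitions = 1, lambda = 0.05, seed = 3)
  # R oracle: z-score on the training pair, fit, count test assignments
  scalp <- scalp_channels(ds)
  idx <- ct$fold_assignments[[1]]
  tr_ds <- select_conditions(ds, c("a", "b"))
  te_ds <- select_conditions(ds, "c")
  oracle <- vapply(seq_along(ds$times), function(t) {
    zs <- zscore_train_apply(tr_ds$data[idx, scalp, t],
                             te_ds$data[, scalp, t])
    fit <- lda_shrink(zs$train, tr_ds$labels[idx] == "a", lambda = 0.05)
    mean(predict(fit, zs$test) == 1)
  }, numeric(1))
  expect_equal(as.vector(ct$accuracies), oracle)
  expect_error(
    cross_classify_timecourse(ds, condition_pair("a", "b"), "a"),
    "must not be part")
})

test_that("a condition matching the trained target is classified as it", {
  # c carries the same pattern as a (the target): score -> 1 inside window
  topo <- make_topography(31, 6)
  efs <- list(
    effect_spec(c("a", "c"), c(0, 200), amplitude = 6, topography = topo))
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 24,
                    conditions = c("a", "b", "c"), n_scalp_channels = 6,
                    sfreq = 40, epoch_window = c(-100, 300),
                    effects = efs, amplitude_jitter_sd = 0, seed = 14)
  ds <- simulate_subject(cfg, 1)$epochs
  ct <- cross_classify_timecourse(ds, condition_pair("a", "b"), "c",
                                  n_repetitions = 1, seed = 2)
  m <- colMeans(ct$accuracies)
  inside <- ct$times >= 25 & ct$times < 175
  expect_gt(mean(m[inside]), 0.95)
  before <- ct$times < 0
  expect_lt(abs(mean(m[before]) - 0.5), 0.25)
})

test_that("temporal generalization is diagonal-consistent and respects topography orthogonality", {
  # two effects with orthogonal topographies in disjoint windows
  t1 <- make_topography(1, 8)
  t2_raw <- make_topography(2, 8)
  t2 <- t2_raw - sum(t2_raw * t1) * t1
  t2 <- t2 / sqrt(sum(t2^2))
  efs <- list(
    effect_spec(c("a", "c"), c(0, 120), amplitude = 6, topography = t1),
    effect_spec(c("a", "c"), c(240, 360), amplitude = 6, topography = t2))
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 24,
                    conditions = c("a", "b", "c"), n_scalp_channels = 8,
                    sfreq = 25, epoch_window = c(-120, 400),
                    effects = efs, amplitude_jitter_sd = 0, seed = 19)
  ds <- simulate_subject(cfg, 1)$epochs
  ct <- cross_classify_timecourse(ds, condition_pair("a", "b"), "c",
                                  n_repetitions = 2, seed = 4)
  tg <- temporal_generalization(ds, condition_pair("a", "b"), "c",
                                n_repetitions = 2, seed = 4)
  expect_identical(diag(tg$values), as.vector(colMeans(ct$accuracies)))
  w1 <- tg$times >= 0 & tg$times < 120
  w2 <- tg$times >= 240 & tg$times < 360
  # on-diagonal blocks decode, cross-window blocks do not generalize
  expect_gt(mean(tg$values[w1, w1]), 0.85)
  expect_gt(mean(tg$values[w2, w2]), 0.85)
  expect_lt(abs(mean(tg$values[w1, w2]) - 0.5), 0.15)
  expect_lt(abs(mean(tg$values[w2, w1]) - 0.5), 0.15)
})

test_that("a stationary pattern generalizes across its whole window", {
  topo <- make_topography(6, 8)
  efs <- list(effect_spec(c("a", "c"), c(100, 400), amplitude = 6,
                          topography = topo))
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 24,
                    conditions = c("a", "b", "c"), n_scalp_channels = 8,
                    sfreq = 25, epoch_window = c(-100, 400),
                    effects = efs, amplitude_jitter_sd = 0, seed = 27)
  ds <- simulate_subject(cfg, 1)$epochs
  tg <- temporal_generalization(ds, condition_pair("a", "b"), "c",
                                n_repetitions = 1, seed = 4)
  w <- tg$times >= 100 & tg$times < 400
  expect_gt(min(tg$values[w, w]), 0.8) # near-square block
})
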