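test_that("peak_to_peak follows its definition", {
  expect_equal(peak_to_peak(rep(3, 10)), 0)
  expect_equal(peak_to_peak(c(0, 3, -2, 1)), 5)
  s <- sin(2 * pi * (0:63) / 16) # 4 cycles, 16 points/cycle
  expect_lt(abs(peak_to_peak(s) - 2), 0.1)
  expect_error(peak_to_peak(c(1, NaN)), "NaN")
  expect_error(peak_to_peak(numeric(0)), "non-empty")
})

test_that("auto_threshold keeps everything when signals are identical", {
  sig <- matrix(rep(sin(1:20), 5), nrow = 5, byrow = TRUE)
  res <- auto_threshold(sig)
  expect_true(all(res$kept))
  expect_equal(min(res$objective$objective), 0)
})

test_that("auto_threshold isolates a gross outlier", {
  set.seed(1)
  sig <- matrix(rnorm(10 * 30), nrow = 10)
  sig[10, ] <- sig[10, ] * 100
  res <- auto_threshold(sig)
  expect_false(res$kept[10])
  expect_true(all(res$kept[1:9]))
  expect_lt(res$threshold, peak_to_peak(sig[10, ]))
  expect_error(auto_threshold(sig[1, , drop = FALSE]), "at least 2")
})

test_that("auto_threshold equals exhaustive objective search and is order-invariant", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(5:20, 1)
    sig <- matrix(rnorm(n * 25, sd = sample(c(1, 1, 5), n, replace = TRUE)),
                  nrow = n)
    res <- auto_threshold(sig)
    expect_equal(res$threshold, auto_threshold_oracle(sig))
    # permutation of the rows picks the same threshold and kept set
    perm <- sample(n)
    res_p <- auto_threshold(sig[perm, , drop = FALSE])
    expect_equal(res_p$threshold, res$threshold)
    expect_equal(res_p$kept, res$kept[perm])
  }
})

test_that("interpolation reproduces weighted-mean oracles", {
  pos <- matrix(c(1, 0, 0, 0, 1, 0, -1, 0, 0, 0, -1, 0), ncol = 3,
                byrow = TRUE)
  # all good electrodes identical -> interpolated equals that signal
  s <- sin(1:15)
  td <- rbind(s, s, s, rnorm(15))
  out <- interpolate_channels(td, bad = 4, positions = pos)
  expect_equal(out[4, ], s, ignore_attr = TRUE)
  expect_identical(out[1:3, ], td[1:3, ]) # good electrodes untouched
  # bad electrode equidistant from two goods -> plain average
  pos2 <- matrix(c(0, 1, 0, 0, -1, 0, 1, 0, 0, 0, 0, 1), ncol = 3,
                 byrow = TRUE)
  td2 <- rbind(sin(1:10), cos(1:10), rnorm(10), rnorm(10))
  out2 <- interpolate_channels(td2, bad = 3, positions = pos2)
  d13 <- sqrt(sum((pos2[1, ] - pos2[3, ])^2))
  d23 <- sqrt(sum((pos2[2, ] - pos2[3, ])^2))
  expect_equal(d13, d23) # geometry really is symmetric
  w4 <- 1 / sqrt(sum((pos2[4, ] - pos2[3, ])^2))
  w <- c(1 / d13, 1 / d23, w4); w <- w / sum(w)
  expect_equal(out2[3, ], w[1] * td2[1, ] + w[2] * td2[2, ] + w[3] * td2[4, ],
               ignore_attr = TRUE)
  # random geometry against a brute-force weighted sum
  set.seed(9)
  posr <- matrix(rnorm(18), ncol = 3)
  posr <- posr / sqrt(rowSums(posr^2))
  tdr <- matrix(rnorm(6 * 12), nrow = 6)
  outr <- interpolate_channels(tdr, bad = 2, positions = posr)
  dists <- sqrt(rowSums(sweep(posr[-2, ], 2, posr[2, ])^2))
  wr <- (1 / dists) / sum(1 / dists)
  expect_equal(outr[2, ], as.vector(wr %*% tdr[-2, ]), ignore_attr = TRUE)
  expect_error(interpolate_channels(tdr, bad = 1:4, positions = posr),
               "at least 3")
})

test_that("clean data pass through with no exclusions and few interpolations", {
  rates <- numeric(0)
  for (seed in 1:20) {
    cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 32,
                      conditions = c("a", "b"), n_scalp_channels = 24,
                      sfreq = 100, epoch_window = c(-500, 500), seed = seed)
    res <- reject_artifacts(simulate_subject(cfg, 1)$epochs)
    expect_equal(length(res$report$excluded_trials), 0)
    rates <- c(rates, res$report$rate_data_rejected)
  }
  expect_lt(max(rates), 0.05)
})

test_that("implanted artifacts are recovered; clean trials survive", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 32,
                    conditions = c("a", "b"), n_scalp_channels = 63,
                    sfreq = 250, artifact_trial_fraction = 0.05,
                    artifact_channel_fraction = 1 / 63,
                    artifact_multiplier = 10, seed = 17)
  s <- simulate_subject(cfg, 1)
  res <- reject_artifacts(s$epochs)
  tp <- s$truth$artifact_pairs
  hit <- apply(tp, 1, function(pr) {
    any(res$report$interpolated$trial == pr[1] &
          res$report$interpolated$channel == pr[2]) ||
      pr[1] %in% res$report$excluded_trials
  })
  expect_gte(mean(hit), 0.95)
  expect_equal(length(setdiff(res$report$excluded_trials, tp[, "trial"])), 0)
  # bad_mask reflects the interpolations on surviving trials
  kept <- res$report$kept_trials
  for (r in which(res$report$interpolated$trial %in% kept)) {
    i <- match(res$report$interpolated$trial[r], kept)
    expect_true(res$epochs$bad_mask[i, res$report$interpolated$channel[r]])
  }
})

test_that("a trial with most electrodes bad is excluded, not repaired", {
  s <- quick_sim(5, n_trials = 16, n_ch = 63, sfreq = 50)
  ds <- s$epochs
  scalp <- scalp_channels(ds)
  ds$data[7, scalp[1:60], ] <- ds$data[7, scalp[1:60], ] * 50
  res <- reject_artifacts(ds)
  expect_true(7 %in% res$report$excluded_trials)
  expect_equal(n_trials(res$epochs), n_trials(ds) -
                 length(res$report$excluded_trials))
})

test_that("rejection recall grows with artifact magnitude", {
  recall_at <- function(mult) {
    cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 32,
                      conditions = c("a", "b"), n_scalp_channels = 24,
                      sfreq = 100, epoch_window = c(-100, 100),
                      artifact_trial_fraction = 0.1,
                      artifact_channel_fraction = 1 / 24,
                      artifact_multiplier = mult, seed = 23)
    s <- simulate_subject(cfg, 1)
    res <- reject_artifacts(s$epochs)
    tp <- s$truth$artifact_pairs
    mean(apply(tp, 1, function(pr) {
      any(res$report$interpolated$trial == pr[1] &
            res$report$interpolated$channel == pr[2]) ||
        pr[1] %in% res$report$excluded_trials
    }))
  }
  r <- c(recall_at(1.2), recall_at(3), recall_at(10))
  expect_true(all(diff(r) >= 0))
  expect_equal(r[3], 1)
})
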