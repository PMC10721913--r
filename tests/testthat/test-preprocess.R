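make_signal_epochs <- function(signal, sfreq, t0 = -500) {
  # one trial, one scalp channel carrying `signal`
  toy_epochs(array(signal, dim = c(1, 1, length(signal))), sfreq = sfreq,
             t0 = t0, labels = "a")
}

test_that("the band-pass removes DC and preserves in-band sinusoids at zero lag", {
  sfreq <- 1000
  n <- 1000
  t <- (0:(n - 1)) / sfreq
  # DC
  dc <- make_signal_epochs(rep(2, n), sfreq)
  out <- eeg_bandpass(dc, c(0.5, 40))
  expect_lt(max(abs(out$data)), 0.02) # < 1% of amplitude everywhere
  # 10 Hz unit sine: gain within [0.95, 1.05], cross-correlation peak at
  # lag 0. Amplitudes are measured in the steady-state core of the epoch:
  # the outermost 0.4 s on each side carry the padding transient of the
  # finite kernel and are not a gain measurement.
  s10 <- sin(2 * pi * 10 * t)
  f10 <- as.vector(eeg_bandpass(make_signal_epochs(s10, sfreq), c(0.5, 40))$data)
  core <- 420:580
  gain <- max(abs(f10[core]))
  expect_gt(gain, 0.95)
  expect_lt(gain, 1.05)
  cc <- stats::ccf(f10, s10, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # 80 Hz unit sine: stop-band amplitude below 0.05
  s80 <- sin(2 * pi * 80 * t)
  f80 <- as.vector(eeg_bandpass(make_signal_epochs(s80, sfreq), c(0.5, 40))$data)
  expect_lt(max(abs(f80[core])), 0.05)
  expect_error(eeg_bandpass(make_signal_epochs(s10, sfreq), c(0.5, 600)),
               "Nyquist")
})

test_that("spectral resampling matches direct sampling of band-limited signals", {
  sfreq <- 1000
  n <- 1000
  t_hi <- -0.5 + (0:(n - 1)) / sfreq
  s <- sin(2 * pi * 10 * t_hi)
  ds <- make_signal_epochs(s, sfreq)
  down <- eeg_resample(ds, 250)
  expect_equal(n_times(down), 250) # ratio 4
  expect_equal(down$sfreq, 250)
  t_lo <- -0.5 + (0:249) / 250
  direct <- sin(2 * pi * 10 * t_lo)
  expect_lt(max(abs(as.vector(down$data) - direct)), 1e-3)
  # identity and error cases
  expect_identical(eeg_resample(ds, 1000), ds)
  expect_error(eeg_resample(ds, 2000), "Upsampling")
  ds101 <- make_signal_epochs(s[1:101], sfreq) # 101 samples, ratio 1/4
  expect_error(eeg_resample(ds101, 250), "Non-integer")
})

test_that("mastoid re-referencing subtracts the reference average", {
  dat <- array(rnorm(4 * 3 * 10), dim = c(4, 3, 10))
  dat[, 2, ] <- 1 # M1
  dat[, 3, ] <- 3 # M2
  ds <- toy_epochs(dat, sfreq = 100, roles = c("scalp", "mastoid", "mastoid"))
  ds$channels$name <- c("C01", "M1", "M2")
  out <- eeg_rereference(ds, c("M1", "M2"))
  expect_equal(out$data[, 1, ], dat[, 1, ] - 2) # every channel shifted by -2
  # mean of the two mastoids is 0 at every sample
  expect_equal(max(abs((out$data[, 2, ] + out$data[, 3, ]) / 2)), 0)
  # identically-zero references leave data unchanged
  dat0 <- dat; dat0[, 2:3, ] <- 0
  ds0 <- ds; ds0$data <- dat0
  expect_equal(eeg_rereference(ds0, c("M1", "M2"))$data, dat0)
  expect_error(eeg_rereference(ds, c("M1", "M9")), "M9")
})

test_that("epoch cropping uses half-open windows on the analysis grid", {
  dat <- array(rnorm(2 * 2 * 250), dim = c(2, 2, 250))
  ds <- toy_epochs(dat, sfreq = 250, t0 = -500)
  expect_equal(n_times(eeg_crop(ds, c(-500, 500))), 250)
  expect_equal(n_times(eeg_crop(ds, c(-100, 500))), 150)
  expect_identical(eeg_crop(ds, c(-500, 500))$data, ds$data)
  expect_error(eeg_crop(ds, c(900, 1000)), "no samples")
})

test_that("baseline correction zeroes the baseline mean per trial and channel", {
  dat <- array(rnorm(3 * 2 * 50), dim = c(3, 2, 50))
  ds <- toy_epochs(dat, sfreq = 100, t0 = -200)
  out <- eeg_baseline(ds, c(-200, 0))
  idx <- which(out$times >= -200 & out$times < 0)
  bl <- apply(out$data[, , idx], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-10)
  # constant trace becomes all zeros
  dsc <- toy_epochs(array(7, dim = c(1, 1, 50)), sfreq = 100, t0 = -200)
  expect_equal(max(abs(eeg_baseline(dsc, c(-200, 0))$data)), 0)
  # hand computation: baseline samples [1, 3] -> subtract 2
  v <- c(1, 3, 5, 7)
  dsv <- toy_epochs(array(v, dim = c(1, 1, 4)), sfreq = 1000, t0 = -2)
  out_v <- eeg_baseline(dsv, c(-2, 0))
  expect_equal(as.vector(out_v$data), v - 2)
})

test_that("the full chain is deterministic and preserves metadata", {
  s <- quick_sim(3, n_trials = 6, n_ch = 4, sfreq = 200, window = c(-500, 500))
  ds <- s$epochs # simulated montage already carries mastoids M1, M2
  cfgp <- preproc_config(target_sfreq = 100, band = c(0.5, 40),
                         reference = c("M1", "M2"))
  out1 <- preprocess(ds, cfgp)
  out2 <- preprocess(ds, cfgp)
  expect_identical(out1$data, out2$data)
  expect_identical(out1$labels, ds$labels)
  expect_identical(out1$channels, ds$channels)
  expect_equal(out1$sfreq, 100)
  idx <- which(out1$times >= -200 & out1$times < 0)
  expect_lt(max(abs(apply(out1$data[, , idx], c(1, 2), mean))), 1e-10)
})

test_that("preprocessing configs are validated", {
  expect_error(preproc_config(band = c(0, 40)), "0 < low")
  expect_error(preproc_config(band = c(0.5, 200)), "0 < low")
  expect_error(preproc_config(baseline_window = c(-600, 0)), "inside")
})
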