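#' Preprocessing configuration
#'
#' Defaults follow a standard visual-ERP decoding pipeline: downsample to
#' 250 Hz, band-pass 0.5-40 Hz with a zero-phase filter, re-reference to
#' the average of the two mastoids, keep the full \[-500, 500) ms epoch and
#' baseline-correct on \[-200, 0) ms. All windows are half-open
#' `[start, end)`.
#'
#' @param target_sfreq target sampling rate (Hz).
#' @param band `c(low, high)` pass-band edges in Hz.
#' @param reference names of the reference channels.
#' @param epoch_window epoch crop window (ms).
#' @param baseline_window baseline window (ms); must lie inside
#'   `epoch_window`.
#' @return an object of class `preproc_config`.
#' @export
preproc_config <- function(target_sfreq = 250,
                           band = c(0.5, 40),
                           reference = c("M1", "M2"),
                           epoch_window = c(-500, 500),
                           baseline_window = c(-200, 0)) {
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < target_sfreq / 2)) {
    stop_eegmvpa("Need 0 < low < high < target_sfreq/2.")
  }
  if (baseline_window[1] < epoch_window[1] || baseline_window[2] > epoch_window[2]) {
    stop_eegmvpa("`baseline_window` must lie inside `epoch_window`.")
  }
  structure(list(
    target_sfreq = target_sfreq, band = as.numeric(band),
    reference = as.character(reference),
    epoch_window = as.numeric(epoch_window),
    baseline_window = as.numeric(baseline_window)
  ), class = "preproc_config")
}

# Real, symmetric (hence exactly zero-phase) transfer function with
# raised-cosine transitions. `freqs` are FFT bin frequencies in Hz.
bandpass_response <- function(freqs, band, trans_low = 0.5, trans_high = 10) {
  f <- abs(freqs)
  lo1 <- max(band[1] - trans_low / 2, 0)
  lo2 <- band[1] + trans_low / 2
  hi1 <- band[2] - trans_high / 2
  hi2 <- band[2] + trans_high / 2
  H <- numeric(length(f))
  H[f >= lo2 & f <= hi1] <- 1
  ramp <- f > lo1 & f < lo2
  H[ramp] <- 0.5 * (1 - cos(pi * (f[ramp] - lo1) / (lo2 - lo1)))
  fall <- f > hi1 & f < hi2
  H[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi1) / (hi2 - hi1)))
  H[f == 0] <- 0
  H
}

# Symmetric (zero-phase) band-pass FIR kernel of half-length L: the ideal
# raised-cosine-transition response is sampled on a dense frequency grid,
# inverse-transformed, Hann-tapered to compact support and re-centred for
# an exactly zero DC gain. Returns the 2L+1 coefficients, lags -L..L.
fir_kernel <- function(sfreq, band, L, trans_low = 0.5, trans_high = 10) {
  M <- stats::nextn(max(8L * L, 1024L), 2)
  freqs <- c(0:(M %/% 2), -((M - M %/% 2 - 1):1)) * sfreq / M
  H <- bandpass_response(freqs, band, trans_low, trans_high)
  g_full <- Re(stats::fft(H, inverse = TRUE)) / M # real, even in the lag
  g <- c(rev(g_full[2:(L + 1)]), g_full[1], g_full[2:(L + 1)])
  taper <- 0.5 * (1 + cos(pi * (-L:L) / (L + 1)))
  g <- g * taper
  g - mean(g) # exact null at DC
}

# Apply the zero-phase FIR to a [time x traces] matrix: odd-reflection
# padding of length L on both sides, then exact linear convolution with the
# symmetric kernel via FFT (the kernel never reaches past the padding, so
# no wrap-around artifacts). Chunking keeps memory bounded.
filter_matrix <- function(x, sfreq, band, trans_low = 0.5, trans_high = 10) {
  n <- nrow(x)
  # 0.4 s half-length: long enough for a steep low edge, short enough that
  # padding transients stay confined near the epoch boundaries
  L <- min(n - 1L, as.integer(ceiling(0.4 * sfreq)))
  g <- fir_kernel(sfreq, band, L, trans_low, trans_high)
  nfft <- stats::nextn(n + 2L * L, 2)
  # kernel centred at lag 0 in the circular buffer
  gbuf <- numeric(nfft)
  gbuf[1:(L + 1)] <- g[(L + 1):(2 * L + 1)]
  gbuf[(nfft - L + 1):nfft] <- g[1:L]
  G <- stats::fft(gbuf)
  idx_pre <- (L + 1L):2L
  idx_post <- (n - 1L):(n - L)
  out <- x
  chunk <- max(1L, floor(4e6 / nfft))
  for (start in seq(1L, ncol(x), by = chunk)) {
    cols <- start:min(ncol(x), start + chunk - 1L)
    xc <- x[, cols, drop = FALSE]
    padded <- rbind(
      2 * matrix(xc[1L, ], L, length(cols), byrow = TRUE) -
        xc[idx_pre, , drop = FALSE],
      xc,
      2 * matrix(xc[n, ], L, length(cols), byrow = TRUE) -
        xc[idx_post, , drop = FALSE],
      matrix(0, nfft - n - 2L * L, length(cols))
    )
    Y <- mvfft(padded) * G
    y <- Re(mvfft(Y, inverse = TRUE)) / nfft
    out[, cols] <- y[(L + 1L):(L + n), , drop = FALSE]
  }
  out
}

#' Zero-phase band-pass filter
#'
#' Filters every trial and channel with a zero-phase band-pass: the epoch is
#' extended by odd reflection at both ends (suppressing edge transients) and
#' multiplied in the frequency domain by a real, symmetric transfer function
#' with raised-cosine transitions (0.5 Hz wide at the low edge, 10 Hz at the
#' high edge). A real symmetric response has zero phase by construction, so
#' in-band components are passed without delay; DC is removed exactly.
#'
#' @param ds an [eeg_epochs()].
#' @param band `c(low, high)` in Hz; `high` must be below Nyquist.
#' @return a filtered `eeg_epochs` with unchanged dimensions and metadata.
#' @export
eeg_bandpass <- function(ds, band = c(0.5, 40)) {
  if (band[2] >= ds$sfreq / 2) {
    stop_eegmvpa(sprintf("Band edge %g Hz is at or above Nyquist (%g Hz).",
                         band[2], ds$sfreq / 2))
  }
  if (band[1] <= 0 || band[1] >= band[2]) {
    stop_eegmvpa("Need 0 < low < high.")
  }
  d <- dim(ds$data)
  # [time x (trial*channel)]
  x <- t(matrix(ds$data, d[1] * d[2], d[3]))
  y <- filter_matrix(x, ds$sfreq, band)
  ds$data <- array(t(y), dim = d)
  ds
}

#' Spectral resampling to a lower rate
#'
#' Resamples each trace in the Fourier domain (truncating the spectrum at
#' the new Nyquist frequency), the approach used by mainstream M/EEG
#' toolboxes. Only downsampling with an integer number of output samples is
#' supported; for band-limited content the result equals direct sampling at
#' the target rate. The time axis is recomputed from the first timepoint.
#'
#' @param ds an [eeg_epochs()].
#' @param target_sfreq target rate in Hz; must not exceed `ds$sfreq`, and
#'   `n_times * target_sfreq / sfreq` must be an integer.
#' @return a resampled `eeg_epochs`.
#' @export
eeg_resample <- function(ds, target_sfreq) {
  if (target_sfreq > ds$sfreq) {
    stop_eegmvpa("Upsampling is not supported (target_sfreq > sfreq).")
  }
  if (target_sfreq == ds$sfreq) return(ds)
  d <- dim(ds$data)
  n <- d[3]
  n_new_real <- n * target_sfreq / ds$sfreq
  if (abs(n_new_real - round(n_new_real)) > 1e-9) {
    stop_eegmvpa(sprintf(
      "Non-integer resampling: %d samples at ratio %g/%g.", n,
      target_sfreq, ds$sfreq))
  }
  n_new <- as.integer(round(n_new_real))
  x <- t(matrix(ds$data, d[1] * d[2], n)) # [time x traces]
  X <- mvfft(x)
  keep_pos <- 1:(n_new %/% 2 + 1L) # DC .. new Nyquist
  keep_neg <- if (n_new > 2) (n - (n_new - n_new %/% 2 - 1L) + 1L):n else integer(0)
  Xn <- X[c(keep_pos, keep_neg), , drop = FALSE]
  # halve the (real) Nyquist bin of the shortened spectrum if n_new is even
  if (n_new %% 2 == 0) Xn[n_new %/% 2 + 1L, ] <- Re(Xn[n_new %/% 2 + 1L, ])
  y <- Re(mvfft(Xn, inverse = TRUE)) / n
  ds$data <- array(t(y), dim = c(d[1], d[2], n_new))
  ds$sfreq <- target_sfreq
  ds$times <- ds$times[1] + (0:(n_new - 1L)) * 1000 / target_sfreq
  validate_epochs(ds)
  ds
}

#' Re-reference to the average of named channels
#'
#' Subtracts the mean of the reference channels (typically the two
#' mastoids) from every channel at every trial and timepoint. Afterwards the
#' mean of the reference channels is identically zero.
#'
#' @param ds an [eeg_epochs()].
#' @param reference character vector of reference channel names.
#' @return a re-referenced `eeg_epochs`.
#' @export
eeg_rereference <- function(ds, reference = c("M1", "M2")) {
  idx <- match(reference, ds$channels$name)
  if (anyNA(idx)) {
    stop_eegmvpa(paste0("Reference channel(s) not found: ",
                        paste(reference[is.na(idx)], collapse = ", ")))
  }
  d <- dim(ds$data)
  ref <- ds$data[, idx, , drop = FALSE]
  ref_mean <- apply(ref, c(1, 3), mean) # [trial x time]
  ds$data <- ds$data - aperm(array(ref_mean, dim = c(d[1], d[3], d[2])),
                             c(1, 3, 2))
  ds
}

#' Crop the epoch to a half-open time window
#'
#' Keeps samples with `window[1] <= t < window[2]`. At 250 Hz the window
#' \[-100, 500) yields exactly 150 samples.
#'
#' @param ds an [eeg_epochs()].
#' @param window `c(start, end)` in ms.
#' @return a cropped `eeg_epochs`.
#' @export
eeg_crop <- function(ds, window) {
  keep <- which(ds$times >= window[1] - 1e-9 & ds$times < window[2] - 1e-9)
  if (!length(keep)) {
    stop_eegmvpa(sprintf("Crop window [%g, %g) contains no samples.",
                         window[1], window[2]))
  }
  ds$data <- ds$data[, , keep, drop = FALSE]
  ds$times <- ds$times[keep]
  ds
}

#' Baseline correction
#'
#' Per trial and channel, subtracts the mean over the baseline window
#' (half-open), so the baseline mean is zero afterwards.
#'
#' @param ds an [eeg_epochs()].
#' @param baseline_window `c(start, end)` in ms.
#' @return a baseline-corrected `eeg_epochs`.
#' @export
eeg_baseline <- function(ds, baseline_window = c(-200, 0)) {
  idx <- which(ds$times >= baseline_window[1] - 1e-9 &
                 ds$times < baseline_window[2] - 1e-9)
  if (!length(idx)) {
    stop_eegmvpa(sprintf("Baseline window [%g, %g) contains no samples.",
                         baseline_window[1], baseline_window[2]))
  }
  d <- dim(ds$data)
  bl <- apply(ds$data[, , idx, drop = FALSE], c(1, 2), mean) # [trial x channel]
  ds$data <- ds$data - array(bl, dim = d)
  ds
}

#' Full preprocessing chain
#'
#' Applies, in order: spectral resampling, zero-phase band-pass,
#' re-referencing to the configured reference channels, epoch cropping and
#' baseline correction. The chain is deterministic: the same input always
#' yields bitwise-identical output. Trial labels and channel metadata are
#' never altered.
#'
#' @param ds an [eeg_epochs()].
#' @param config a [preproc_config()].
#' @return a preprocessed `eeg_epochs`.
#' @export
preprocess <- function(ds, config = preproc_config()) {
  stopifnot(inherits(config, "preproc_config"))
  ds |>
    eeg_resample(config$target_sfreq) |>
    eeg_bandpass(config$band) |>
    eeg_rereference(config$reference) |>
    eeg_crop(config$epoch_window) |>
    eeg_baseline(config$baseline_window)
}
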