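#' Deterministic pseudo-random scalp topography
#'
#' Draws a standard-normal weight vector over channels from its own seed and
#' scales it to unit Euclidean norm. Used to give simulated category effects
#' a fixed, reproducible spatial pattern.
#'
#' @param seed integer seed; the same seed always yields the same vector.
#' @param n_channels number of channels (>= 1).
#' @return numeric vector of length `n_channels` with `sqrt(sum(w^2)) == 1`.
#' @export
make_topography <- function(seed, n_channels) {
  if (!is_count(n_channels, min = 1L)) {
    stop_eegmvpa("`n_channels` must be a positive integer.")
  }
  w <- with_seed(seed, rnorm(n_channels))
  w / sqrt(sum(w^2))
}

#' Specify one simulated category effect
#'
#' An effect is a rank-one spatiotemporal pattern: a unit-norm scalp
#' topography times a temporal envelope, added (scaled by `amplitude`, in
#' microvolts) to every trial of the carrying conditions. A single effect
#' shared by several conditions is the synthetic analogue of
#' cross-condition generalization.
#'
#' @param conditions condition ids carrying the pattern.
#' @param window `c(t_start, t_end)` in ms, half-open `[t_start, t_end)`.
#' @param amplitude pattern strength in microvolts (>= 0).
#' @param envelope `"boxcar"` (constant 1 inside the window) or `"halfcos"`
#'   (half-cosine bump rising from and returning to 0).
#' @param topography optional explicit channel-weight vector over scalp
#'   channels (will be normalised to unit norm); if `NULL`, drawn from
#'   `topography_seed` via [make_topography()].
#' @param topography_seed seed for the drawn topography.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(conditions, window, amplitude,
                        envelope = c("boxcar", "halfcos"),
                        topography = NULL, topography_seed = 1L) {
  envelope <- match.arg(envelope)
  if (length(window) != 2L || window[2] <= window[1]) {
    stop_eegmvpa("`window` must be c(start, end) with end > start.")
  }
  if (amplitude < 0) stop_eegmvpa("`amplitude` must be >= 0.")
  structure(list(
    conditions = as.character(conditions),
    window = as.numeric(window),
    amplitude = as.numeric(amplitude),
    envelope = envelope,
    topography = topography,
    topography_seed = as.integer(topography_seed)
  ), class = "effect_spec")
}

#' Simulation configuration
#'
#' Defaults mirror the emulated study design: 14 subjects, 4 conditions
#' (hands, tools, feet, animals) with 128 trials each (512 total), 63 scalp
#' channels plus two mastoids, 1000 Hz sampling, epochs spanning
#' \[-500, 500) ms. Noise defaults to an AR(1) process (lag-one correlation
#' 0.5, stationary SD `noise_sd`) for EEG-like temporal autocorrelation;
#' white noise is available for analytic checks. Artifacts are implanted by
#' scaling selected trial x electrode segments so their peak-to-peak
#' amplitude equals `artifact_multiplier` times the 99th percentile of the
#' clean peak-to-peak distribution.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_condition trials per condition.
#' @param conditions condition ids.
#' @param n_scalp_channels scalp electrode count (two mastoids are added).
#' @param sfreq native sampling rate in Hz.
#' @param epoch_window epoch span `c(start, end)` ms, half-open.
#' @param noise_sd stationary noise SD in microvolts.
#' @param noise_model `"ar1"` or `"white"`.
#' @param ar_coef AR(1) coefficient (ignored for white noise).
#' @param effects list of [effect_spec()] objects.
#' @param artifact_trial_fraction fraction of trials receiving artifacts.
#' @param artifact_channel_fraction fraction of scalp electrodes affected in
#'   each artifact trial (at least one).
#' @param artifact_multiplier peak-to-peak scaling of implanted artifacts.
#' @param amplitude_jitter_sd between-subject SD of the per-effect amplitude
#'   multiplier (0.2 = 20% of the nominal amplitude; 0 disables jitter).
#' @param seed master seed; every subject derives its own stream from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 14L,
                       n_trials_per_condition = 128L,
                       conditions = c("hands", "tools", "feet", "animals"),
                       n_scalp_channels = 63L,
                       sfreq = 1000,
                       epoch_window = c(-500, 500),
                       noise_sd = 1,
                       noise_model = c("ar1", "white"),
                       ar_coef = 0.5,
                       effects = list(),
                       artifact_trial_fraction = 0,
                       artifact_channel_fraction = 0,
                       artifact_multiplier = 10,
                       amplitude_jitter_sd = 0.2,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (!is_count(n_subjects)) stop_eegmvpa("`n_subjects` must be a non-negative integer.")
  if (!is_count(n_trials_per_condition, 1L)) {
    stop_eegmvpa("`n_trials_per_condition` must be a positive integer.")
  }
  for (fr in c(artifact_trial_fraction, artifact_channel_fraction)) {
    if (fr < 0 || fr > 1) stop_eegmvpa("artifact fractions must lie in [0, 1].")
  }
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    conditions = as.character(conditions),
    n_scalp_channels = as.integer(n_scalp_channels),
    sfreq = as.numeric(sfreq),
    epoch_window = as.numeric(epoch_window),
    noise_sd = as.numeric(noise_sd),
    noise_model = noise_model,
    ar_coef = as.numeric(ar_coef),
    effects = effects,
    artifact_trial_fraction = as.numeric(artifact_trial_fraction),
    artifact_channel_fraction = as.numeric(artifact_channel_fraction),
    artifact_multiplier = as.numeric(artifact_multiplier),
    amplitude_jitter_sd = as.numeric(amplitude_jitter_sd),
    seed = as.integer(seed)
  ), class = "sim_config")
  times <- sim_times(cfg)
  for (ef in cfg$effects) {
    if (ef$window[1] < cfg$epoch_window[1] || ef$window[2] > cfg$epoch_window[2]) {
      stop_eegmvpa(sprintf("Effect window [%g, %g) lies outside the epoch [%g, %g).",
                           ef$window[1], ef$window[2],
                           cfg$epoch_window[1], cfg$epoch_window[2]))
    }
    bad <- setdiff(ef$conditions, cfg$conditions)
    if (length(bad)) {
      stop_eegmvpa(paste0("Effect references unknown condition(s): ",
                          paste(bad, collapse = ", ")))
    }
  }
  cfg
}

sim_times <- function(cfg) {
  step <- 1000 / cfg$sfreq
  seq(cfg$epoch_window[1], cfg$epoch_window[2] - step / 2, by = step)
}

#' Deterministic electrode montage on the unit sphere
#'
#' Scalp electrodes are placed quasi-uniformly on the upper hemisphere with
#' a Fibonacci lattice; mastoids sit low and lateral. Positions are
#' head-model units on the unit sphere and exist so that spatial
#' interpolation of rejected electrodes is well defined.
#'
#' @param n_scalp number of scalp electrodes.
#' @param mastoids add mastoid channels `M1`, `M2`?
#' @return a tibble with columns `name`, `role`, `x`, `y`, `z`.
#' @export
default_montage <- function(n_scalp = 63L, mastoids = TRUE) {
  i <- seq_len(n_scalp)
  golden <- pi * (3 - sqrt(5))
  z <- 0.15 + (0.995 - 0.15) * (i - 0.5) / n_scalp # upper hemisphere band
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * i
  scalp <- tibble(
    name = sprintf("E%02d", i), role = "scalp",
    x = r * cos(th), y = r * sin(th), z = z
  )
  if (!mastoids) return(scalp)
  m <- tibble(
    name = c("M1", "M2"), role = "mastoid",
    x = c(-0.98, 0.98), y = c(-0.12, -0.12), z = c(-0.16, -0.16)
  )
  nrm <- sqrt(m$x^2 + m$y^2 + m$z^2)
  m$x <- m$x / nrm; m$y <- m$y / nrm; m$z <- m$z / nrm
  dplyr::bind_rows(scalp, m)
}

effect_envelope <- function(ef, times) {
  inside <- times >= ef$window[1] & times < ef$window[2]
  env <- numeric(length(times))
  if (ef$envelope == "boxcar") {
    env[inside] <- 1
  } else {
    u <- (times[inside] - ef$window[1]) / diff(ef$window)
    env[inside] <- 0.5 * (1 - cos(2 * pi * u)) # half-cosine bump, peak 1
  }
  env
}

#' Simulate one subject's epoched EEG with known ground truth
#'
#' Each trial is the sum of the configured condition effects (rank-one
#' topography x envelope patterns) and stationary noise; artifacts are then
#' implanted on randomly chosen trial x electrode segments by scaling them
#' to a peak-to-peak amplitude of `artifact_multiplier` times the 99th
#' percentile of the clean scalp peak-to-peak distribution. Mastoid channels
#' carry noise only. Fully reproducible from `(cfg$seed, subject_index)`.
#'
#' @param cfg a [sim_config()].
#' @param subject_index 1-based subject number.
#' @return a list with elements `epochs` (an [eeg_epochs()]) and `truth`
#'   (effect windows/topographies/subject amplitudes, implanted artifact
#'   trial and `(trial, channel)` pairs).
#' @export
simulate_subject <- function(cfg, subject_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  times <- sim_times(cfg)
  nt <- length(times)
  channels <- default_montage(cfg$n_scalp_channels)
  nch <- nrow(channels)
  ncond <- length(cfg$conditions)
  ntr <- cfg$n_trials_per_condition * ncond
  scalp <- which(channels$role == "scalp")

  with_seed(derive_seed(cfg$seed, 101L, subject_index), {
    labels <- sample(rep(cfg$conditions, each = cfg$n_trials_per_condition))

    # noise: [trial, channel, time]
    if (cfg$noise_model == "white") {
      data <- array(rnorm(ntr * nch * nt, sd = cfg$noise_sd), dim = c(ntr, nch, nt))
    } else {
      rho <- cfg$ar_coef
      innov_sd <- cfg$noise_sd * sqrt(1 - rho^2)
      data <- array(0, dim = c(ntr, nch, nt))
      cur <- matrix(rnorm(ntr * nch, sd = cfg$noise_sd), ntr, nch)
      data[, , 1] <- cur
      for (t in seq_len(nt)[-1]) {
        cur <- rho * cur + matrix(rnorm(ntr * nch, sd = innov_sd), ntr, nch)
        data[, , t] <- cur
      }
    }

    # condition effects
    truth_effects <- list()
    for (j in seq_along(cfg$effects)) {
      ef <- cfg$effects[[j]]
      topo <- ef$topography %||%
        make_topography(derive_seed(cfg$seed, 202L, ef$topography_seed),
                        length(scalp))
      topo <- topo / sqrt(sum(topo^2))
      if (length(topo) != length(scalp)) {
        stop_eegmvpa("Effect topography length must equal the scalp channel count.")
      }
      amp <- ef$amplitude
      if (cfg$amplitude_jitter_sd > 0) {
        amp <- amp * max(0, 1 + rnorm(1, 0, cfg$amplitude_jitter_sd))
      }
      env <- effect_envelope(ef, times)
      pattern <- outer(topo, env) * amp # [scalp x time]
      rows <- which(labels %in% ef$conditions)
      for (tr in rows) {
        data[tr, scalp, ] <- data[tr, scalp, ] + pattern
      }
      truth_effects[[j]] <- list(conditions = ef$conditions, window = ef$window,
                                 amplitude = amp, envelope = ef$envelope,
                                 topography = topo)
    }

    # implant artifacts by peak-to-peak scaling
    art_trials <- integer(0)
    art_pairs <- matrix(integer(0), ncol = 2,
                        dimnames = list(NULL, c("trial", "channel")))
    n_art <- floor(cfg$artifact_trial_fraction * ntr)
    if (n_art > 0) {
      p2p_clean <- apply(data[, scalp, , drop = FALSE], c(1, 2),
                         function(v) max(v) - min(v))
      q99 <- quantile(p2p_clean, 0.99, names = FALSE)
      target <- cfg$artifact_multiplier * q99
      art_trials <- sort(sample(ntr, n_art))
      m <- max(1L, round(cfg$artifact_channel_fraction * length(scalp)))
      for (tr in art_trials) {
        chs <- scalp[sample(length(scalp), m)]
        for (ch in chs) {
          v <- data[tr, ch, ]
          ctr <- mean(v)
          p2p <- max(v) - min(v)
          data[tr, ch, ] <- ctr + (v - ctr) * (target / p2p)
          art_pairs <- rbind(art_pairs, c(tr, ch))
        }
      }
    }

    ds <- eeg_epochs(
      data = data, times = times, sfreq = cfg$sfreq, labels = labels,
      channels = channels,
      subject_id = sprintf("sim%02d", subject_index),
      conditions = cfg$conditions
    )
    list(
      epochs = ds,
      truth = list(
        effects = truth_effects,
        artifact_trials = art_trials,
        artifact_pairs = art_pairs
      )
    )
  })
}

#' Simulate a whole study
#'
#' Generates `cfg$n_subjects` datasets with independent noise and artifact
#' placement but a shared effect structure (up to optional between-subject
#' amplitude jitter), as a group-level analysis expects.
#'
#' @param cfg a [sim_config()].
#' @return a list of `list(epochs=, truth=)`, one per subject; empty list if
#'   `n_subjects` is 0.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lapply(seq_len(cfg$n_subjects), function(s) simulate_subject(cfg, s))
}
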