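#' Peak-to-peak amplitude
#'
#' `max(x) - min(x)`, the standard scalar summary used to flag artifactual
#' M/EEG segments.
#'
#' @param x numeric vector (non-empty, finite).
#' @return non-negative scalar.
#' @export
peak_to_peak <- function(x) {
  if (!length(x)) stop_eegmvpa("`x` must be non-empty.")
  if (anyNA(x) || any(!is.finite(x))) stop_eegmvpa("`x` contains NaN/NA/Inf.")
  max(x) - min(x)
}

#' Data-driven peak-to-peak rejection threshold
#'
#' Given a group of equal-length signals (e.g. all trials of one electrode),
#' finds the peak-to-peak threshold whose under-threshold subset best agrees
#' with the group: candidate thresholds are the observed unique peak-to-peak
#' values (the objective only changes there); for each candidate `theta` the
#' objective is the sum of squared differences between the mean of the
#' signals with p2p <= theta and the pointwise median of *all* signals. The
#' chosen threshold minimises the objective; ties are resolved toward the
#' largest threshold (reject least data).
#'
#' @param signals numeric matrix `[n_signals x n_times]` (rows are signals).
#' @return a list with `threshold` (microvolts), `kept` (logical over rows),
#'   `objective` (tibble of candidate thresholds and objective values).
#' @export
auto_threshold <- function(signals) {
  signals <- as.matrix(signals)
  if (nrow(signals) < 2L) stop_eegmvpa("Need at least 2 signals.")
  p2p <- apply(signals, 1L, peak_to_peak)
  med <- apply(signals, 2L, median)
  ord <- order(p2p)
  # cumulative mean of signals sorted by p2p: mean of the kept set for a
  # threshold equal to the m-th smallest p2p is cum_sums[m, ] / m
  cum_sums <- apply(signals[ord, , drop = FALSE], 2L, cumsum)
  if (nrow(signals) == 2L && is.null(dim(cum_sums))) {
    cum_sums <- matrix(cum_sums, nrow = nrow(signals))
  }
  m_all <- seq_len(nrow(signals))
  J_all <- rowSums((cum_sums / m_all - matrix(med, nrow(signals),
                                              ncol(signals), byrow = TRUE))^2)
  # candidates: unique p2p values; the kept set for candidate theta is all
  # signals with p2p <= theta, i.e. the largest m with sorted-p2p == theta
  cand_m <- which(!duplicated(p2p[ord], fromLast = TRUE))
  cand_theta <- p2p[ord][cand_m]
  cand_J <- J_all[cand_m]
  best <- which(cand_J <= min(cand_J) + 0) # exact ties
  pick <- best[length(best)] # largest theta among minimisers
  threshold <- cand_theta[pick]
  list(
    threshold = threshold,
    kept = p2p <= threshold,
    objective = tibble(threshold = cand_theta, objective = cand_J)
  )
}

#' Inverse-distance interpolation of bad electrodes
#'
#' Replaces each bad electrode's signal by a weighted mean of the good
#' electrodes, with weights proportional to `1 / distance` between
#' unit-sphere electrode positions (normalised to sum to one), applied per
#' timepoint. Good electrodes are untouched.
#'
#' @param trial_data numeric matrix `[n_channels x n_times]` for one trial.
#' @param bad integer indices (rows of `trial_data`) to repair.
#' @param positions numeric matrix `[n_channels x 3]` of electrode
#'   positions.
#' @return the repaired `[n_channels x n_times]` matrix.
#' @export
interpolate_channels <- function(trial_data, bad, positions) {
  bad <- sort(unique(as.integer(bad)))
  good <- setdiff(seq_len(nrow(trial_data)), bad)
  if (length(good) < 3L) stop_eegmvpa("Need at least 3 good electrodes.")
  if (!length(bad)) return(trial_data)
  out <- trial_data
  for (b in bad) {
    dvec <- sqrt(rowSums((positions[good, , drop = FALSE] -
                            matrix(positions[b, ], length(good), 3,
                                   byrow = TRUE))^2))
    dvec <- pmax(dvec, 1e-12)
    w <- (1 / dvec) / sum(1 / dvec)
    out[b, ] <- as.vector(w %*% trial_data[good, , drop = FALSE])
  }
  out
}

# Repair step shared by both passes: trials with bad electrodes are
# interpolated when fewer than half the scalp electrodes are bad, excluded
# otherwise. `bad_by_trial` is a list: trial index -> integer channel ids.
repair_trials <- function(data, bad_by_trial, scalp, positions, bad_mask) {
  n_scalp <- length(scalp)
  excluded <- integer(0)
  interpolated <- matrix(integer(0), ncol = 2,
                         dimnames = list(NULL, c("trial", "channel")))
  for (tr in as.integer(names(bad_by_trial))) {
    chs <- bad_by_trial[[as.character(tr)]]
    if (length(chs) >= n_scalp / 2) {
      excluded <- c(excluded, tr)
    } else {
      bad_in_scalp <- match(chs, scalp)
      data[tr, scalp, ] <- interpolate_channels(
        data[tr, scalp, ], bad_in_scalp, positions)
      new_chs <- chs[!bad_mask[tr, chs]]
      bad_mask[tr, chs] <- TRUE
      if (length(new_chs)) {
        interpolated <- rbind(interpolated,
                              cbind(trial = rep(tr, length(new_chs)),
                                    channel = new_chs))
      }
    }
  }
  list(data = data, excluded = sort(excluded), interpolated = interpolated,
       bad_mask = bad_mask)
}

#' Two-pass automatic artifact rejection
#'
#' Applies the data-driven peak-to-peak threshold ([auto_threshold()])
#' twice: first *across trials for each scalp electrode* (flagging
#' electrode-wise bad trials), then — after repairing — *across electrodes
#' for each trial* (flagging trial-wise bad electrodes). After each pass,
#' every flagged trial is repaired by inverse-distance interpolation of its
#' flagged electrodes if fewer than half the scalp electrodes are flagged,
#' and excluded from the dataset otherwise. Mastoid and EOG channels are
#' never auto-rejected.
#'
#' @param ds an [eeg_epochs()] with at least 2 trials and 2 scalp
#'   electrodes.
#' @return a list with `epochs` (the repaired dataset, excluded trials
#'   dropped, `bad_mask` updated) and `report` (a `rejection_report`:
#'   per-electrode and per-trial thresholds, interpolated pairs, excluded
#'   trials, and summary rates).
#' @export
reject_artifacts <- function(ds) {
  scalp <- scalp_channels(ds)
  if (n_trials(ds) < 2L || length(scalp) < 2L) {
    stop_eegmvpa("Need >= 2 trials and >= 2 scalp electrodes.")
  }
  positions <- as.matrix(ds$channels[scalp, c("x", "y", "z")])
  ntr0 <- n_trials(ds)
  data <- ds$data
  bad_mask <- ds$bad_mask %||% matrix(FALSE, ntr0, n_channels(ds))

  # pass 1: across trials, per electrode
  pass1_thresholds <- numeric(length(scalp))
  bad_by_trial1 <- list()
  for (j in seq_along(scalp)) {
    res <- auto_threshold(data[, scalp[j], , drop = TRUE])
    pass1_thresholds[j] <- res$threshold
    for (tr in which(!res$kept)) {
      key <- as.character(tr)
      bad_by_trial1[[key]] <- c(bad_by_trial1[[key]], scalp[j])
    }
  }
  rep1 <- repair_trials(data, bad_by_trial1, scalp, positions, bad_mask)
  keep1 <- setdiff(seq_len(ntr0), rep1$excluded)
  data <- rep1$data[keep1, , , drop = FALSE]
  bad_mask <- rep1$bad_mask[keep1, , drop = FALSE]

  # pass 2: across electrodes, per trial (on pass-1 repaired data).
  # Electrodes already repaired by interpolation are synthetic (they track
  # the mean of their neighbours) and would bias the data-driven threshold,
  # so they are excluded from the threshold estimation; the half-electrode
  # exclusion rule counts them as already rejected.
  pass2_thresholds <- rep(NA_real_, dim(data)[1])
  bad_by_trial2 <- list()
  for (i in seq_len(dim(data)[1])) {
    raw <- scalp[!bad_mask[i, scalp]]
    if (length(raw) < 2L) next
    res <- auto_threshold(data[i, raw, , drop = TRUE])
    pass2_thresholds[i] <- res$threshold
    already_bad <- scalp[bad_mask[i, scalp]]
    flagged <- c(raw[!res$kept], already_bad)
    if (length(flagged) > length(already_bad)) {
      bad_by_trial2[[as.character(i)]] <- flagged
    } else if (length(already_bad) >= length(scalp) / 2) {
      bad_by_trial2[[as.character(i)]] <- flagged
    }
  }
  rep2 <- repair_trials(data, bad_by_trial2, scalp, positions, bad_mask)
  keep2 <- setdiff(seq_len(dim(data)[1]), rep2$excluded)
  data <- rep2$data[keep2, , , drop = FALSE]
  bad_mask <- rep2$bad_mask[keep2, , drop = FALSE]

  kept_orig <- keep1[keep2] # original trial indices surviving both passes
  excluded_orig <- sort(c(rep1$excluded, keep1[rep2$excluded]))

  interp1 <- rep1$interpolated
  interp2 <- rep2$interpolated
  if (nrow(interp2)) interp2[, "trial"] <- keep1[interp2[, "trial"]]
  interpolated <- rbind(interp1, interp2)
  # drop interpolations on trials later excluded
  if (nrow(interpolated)) {
    interpolated <- interpolated[interpolated[, "trial"] %in% kept_orig, ,
                                 drop = FALSE]
  }

  n_cells <- ntr0 * length(scalp)
  rejected_cells <- nrow(interpolated) + length(excluded_orig) * length(scalp)

  report <- structure(list(
    pass1_thresholds = tibble(channel = ds$channels$name[scalp],
                              threshold = pass1_thresholds),
    pass2_thresholds = tibble(trial = keep1, threshold = pass2_thresholds),
    interpolated = as_tibble(interpolated),
    excluded_trials = excluded_orig,
    kept_trials = kept_orig,
    n_trials_in = ntr0,
    rate_data_rejected = rejected_cells / n_cells,
    rate_trials_excluded = length(excluded_orig) / ntr0
  ), class = "rejection_report")

  out <- ds
  out$data <- data
  out$labels <- ds$labels[kept_orig]
  out$bad_mask <- bad_mask
  validate_epochs(out)
  list(epochs = out, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf(
    "<rejection_report> %d/%d trials excluded (%.1f%%); %d cells interpolated; %.2f%% of data rejected\n",
    length(x$excluded_trials), x$n_trials_in, 100 * x$rate_trials_excluded,
    nrow(x$interpolated), 100 * x$rate_data_rejected))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rejection_report <- function(x, ...) {
  x$interpolated |>
    as_tibble() |>
    dplyr::mutate(action = "interpolated") |>
    dplyr::bind_rows(tibble(trial = x$excluded_trials,
                            channel = NA_integer_, action = "excluded"))
}

#' @exportS3Method generics::glance
glance.rejection_report <- function(x, ...) {
  tibble(
    n_trials_in = x$n_trials_in,
    n_excluded = length(x$excluded_trials),
    n_interpolated_cells = nrow(x$interpolated),
    rate_data_rejected = x$rate_data_rejected,
    rate_trials_excluded = x$rate_trials_excluded
  )
}
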