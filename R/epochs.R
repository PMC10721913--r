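#' Epoched multichannel EEG container
#'
#' `eeg_epochs()` bundles a trials x channels x time array of epoched EEG
#' (microvolts) with its time axis (milliseconds relative to stimulus onset),
#' sampling rate, per-trial condition labels and per-channel metadata. It is
#' the common currency of every pipeline stage: simulation, preprocessing,
#' artifact rejection and decoding all consume and return this class.
#'
#' @param data numeric array `[n_trials, n_channels, n_times]`, in microvolts.
#' @param times numeric vector of timepoints in ms, strictly increasing with
#'   spacing `1000 / sfreq`.
#' @param sfreq sampling rate in Hz.
#' @param labels character vector of per-trial condition labels.
#' @param channels a data frame with columns `name`, `role` (one of
#'   `"scalp"`, `"mastoid"`, `"eog"`) and unit-sphere positions `x`, `y`, `z`.
#'   See [default_montage()].
#' @param subject_id subject identifier string.
#' @param conditions the declared condition set; defaults to the unique
#'   labels in order of first appearance.
#' @param bad_mask optional logical matrix `[n_trials, n_channels]` marking
#'   entries that were repaired by interpolation.
#'
#' @return An object of class `eeg_epochs`.
#' @examples
#' ds <- simulate_subject(sim_config(n_subjects = 1, n_trials_per_condition = 4,
#'   n_scalp_channels = 6, sfreq = 200, seed = 1))$epochs
#' ds
#' n_trials(ds)
#' @export
eeg_epochs <- function(data, times, sfreq, labels, channels,
                       subject_id = "S01", conditions = NULL,
                       bad_mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_eegmvpa("`data` must be a 3-D array [trials x channels x times].")
  }
  channels <- as_tibble(channels)
  conditions <- conditions %||% unique(as.character(labels))
  ds <- structure(
    list(
      data = data,
      times = as.numeric(times),
      sfreq = as.numeric(sfreq),
      labels = as.character(labels),
      channels = channels,
      subject_id = as.character(subject_id),
      conditions = as.character(conditions),
      bad_mask = bad_mask
    ),
    class = "eeg_epochs"
  )
  validate_epochs(ds)
  ds
}

#' Validate an `eeg_epochs` object
#'
#' Checks the class invariants: time-axis length and uniform spacing
#' `1000 / sfreq` (tolerance 1e-9 ms), labels drawn from the declared
#' condition set, unique channel names, known channel roles, and finite
#' channel positions. Called by every constructor and by [read_epochs()].
#'
#' @param ds an `eeg_epochs` object.
#' @return `ds`, invisibly, if valid; otherwise an error naming the
#'   violated field.
#' @export
validate_epochs <- function(ds) {
  d <- dim(ds$data)
  if (length(ds$times) != d[3]) {
    stop_eegmvpa(sprintf(
      "Invalid `times`: length %d does not match n_times %d.",
      length(ds$times), d[3]), class = "eegmvpa_validation_error")
  }
  if (d[3] > 1) {
    dt <- diff(ds$times)
    if (any(dt <= 0) || any(abs(dt - 1000 / ds$sfreq) > 1e-9)) {
      stop_eegmvpa(sprintf(
        "Invalid `times`: spacing must be strictly increasing at %g ms (1000/sfreq).",
        1000 / ds$sfreq), class = "eegmvpa_validation_error")
    }
  }
  if (length(ds$labels) != d[1]) {
    stop_eegmvpa(sprintf(
      "Invalid `labels`: length %d does not match n_trials %d.",
      length(ds$labels), d[1]), class = "eegmvpa_validation_error")
  }
  if (!all(ds$labels %in% ds$conditions)) {
    bad <- setdiff(unique(ds$labels), ds$conditions)
    stop_eegmvpa(paste0("Invalid `labels`: not in declared condition set: ",
                        paste(bad, collapse = ", ")),
                 class = "eegmvpa_validation_error")
  }
  ch <- ds$channels
  if (nrow(ch) != d[2]) {
    stop_eegmvpa(sprintf(
      "Invalid `channels`: %d rows for %d data channels.", nrow(ch), d[2]),
      class = "eegmvpa_validation_error")
  }
  if (!all(c("name", "role", "x", "y", "z") %in% names(ch))) {
    stop_eegmvpa("Invalid `channels`: need columns name, role, x, y, z.",
                 class = "eegmvpa_validation_error")
  }
  if (anyDuplicated(ch$name)) {
    stop_eegmvpa("Invalid `channels`: duplicate channel names.",
                 class = "eegmvpa_validation_error")
  }
  if (!all(ch$role %in% c("scalp", "mastoid", "eog"))) {
    stop_eegmvpa("Invalid `channels`: role must be scalp, mastoid or eog.",
                 class = "eegmvpa_validation_error")
  }
  if (!all(is.finite(ch$x) & is.finite(ch$y) & is.finite(ch$z))) {
    stop_eegmvpa("Invalid `channels`: non-finite position.",
                 class = "eegmvpa_validation_error")
  }
  if (!is.null(ds$bad_mask)) {
    if (!is.logical(ds$bad_mask) || !identical(dim(ds$bad_mask), d[1:2])) {
      stop_eegmvpa("Invalid `bad_mask`: must be logical [n_trials x n_channels].",
                   class = "eegmvpa_validation_error")
    }
  }
  invisible(ds)
}

#' @rdname eeg_epochs
#' @export
n_trials <- function(ds) dim(ds$data)[1]

#' @rdname eeg_epochs
#' @export
n_channels <- function(ds) dim(ds$data)[2]

#' @rdname eeg_epochs
#' @export
n_times <- function(ds) dim(ds$data)[3]

#' Indices of scalp channels (the decoding feature set)
#' @param ds an `eeg_epochs` object.
#' @return integer vector of channel indices with role `"scalp"`.
#' @export
scalp_channels <- function(ds) which(ds$channels$role == "scalp")

#' Per-condition trial counts
#' @param ds an `eeg_epochs` object.
#' @return a tibble with columns `condition` and `n`.
#' @export
count_conditions <- function(ds) {
  tibble(
    condition = ds$conditions,
    n = vapply(ds$conditions, function(cc) sum(ds$labels == cc), integer(1))
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> subject %s: %d trials x %d channels x %d samples\n",
              x$subject_id, d[1], d[2], d[3]))
  cat(sprintf("  time %g..%g ms @ %g Hz; conditions: %s\n",
              min(x$times), max(x$times), x$sfreq,
              paste(sprintf("%s (%d)", count_conditions(x)$condition,
                            count_conditions(x)$n), collapse = ", ")))
  invisible(x)
}

#' Subset an epoched dataset to a set of conditions
#'
#' Keeps only trials whose label is in `conditions`, preserving trial order
#' and leaving the channel set untouched. The declared condition set of the
#' result is the requested set.
#'
#' @param ds an `eeg_epochs` object.
#' @param conditions character vector of condition ids; all must be present
#'   in `ds$conditions`.
#' @return a new `eeg_epochs` with only the selected trials.
#' @export
select_conditions <- function(ds, conditions) {
  unknown <- setdiff(conditions, ds$conditions)
  if (length(unknown)) {
    stop_eegmvpa(paste0("Unknown condition(s): ", paste(unknown, collapse = ", ")))
  }
  keep <- which(ds$labels %in% conditions)
  eeg_epochs(
    data = ds$data[keep, , , drop = FALSE],
    times = ds$times, sfreq = ds$sfreq,
    labels = ds$labels[keep], channels = ds$channels,
    subject_id = ds$subject_id, conditions = conditions,
    bad_mask = if (is.null(ds$bad_mask)) NULL else ds$bad_mask[keep, , drop = FALSE]
  )
}

#' Long-format view of epoched data
#'
#' @param x an `eeg_epochs` object.
#' @param ... unused.
#' @return a tibble with columns `trial`, `condition`, `channel`, `time`,
#'   `amplitude` (microvolts). Large: `n_trials * n_channels * n_times` rows.
#' @exportS3Method generics::tidy
tidy.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    condition = rep(x$labels, times = d[2] * d[3]),
    channel = rep(rep(x$channels$name, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    amplitude = as.vector(x$data)
  )
}

#' @exportS3Method generics::glance
glance.eeg_epochs <- function(x, ...) {
  tibble(
    subject_id = x$subject_id,
    n_trials = n_trials(x), n_channels = n_channels(x), n_times = n_times(x),
    sfreq = x$sfreq, t_min = min(x$times), t_max = max(x$times),
    n_conditions = length(x$conditions),
    n_interpolated = if (is.null(x$bad_mask)) 0L else sum(x$bad_mask)
  )
}
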