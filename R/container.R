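#' Read and write the native epoched-EEG container
#'
#' The native container is a pair of files sharing a base path: a raw binary
#' array store (`<path>.dat`, little-endian IEEE-754 doubles in column-major
#' trials x channels x times order) and a JSON metadata sidecar
#' (`<path>.json`) holding the schema version, dimensions, time axis,
#' sampling rate, labels, condition set and channel table. The round trip is
#' lossless for 64-bit floats.
#'
#' @param ds an `eeg_epochs` object (validated before writing).
#' @param path base path; a trailing `.json` or `.dat` is stripped.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` an
#'   `eeg_epochs`.
#' @examples
#' ds <- simulate_subject(sim_config(n_subjects = 1, n_trials_per_condition = 2,
#'   n_scalp_channels = 3, sfreq = 100, seed = 1))$epochs
#' p <- tempfile()
#' write_epochs(ds, p)
#' identical(read_epochs(p)$data, ds$data)
#' @export
write_epochs <- function(ds, path) {
  validate_epochs(ds)
  path <- sub("\\.(json|dat)$", "", path)
  meta <- list(
    schema = "eegmvpa-epochs",
    schema_version = 1L,
    subject_id = ds$subject_id,
    dims = dim(ds$data),
    sfreq = ds$sfreq,
    times = ds$times,
    labels = ds$labels,
    conditions = ds$conditions,
    channels = as.data.frame(ds$channels),
    byte_order = "little",
    dtype = "float64",
    data_file = paste0(basename(path), ".dat")
  )
  if (!is.null(ds$bad_mask)) {
    meta$bad_mask_which <- which(ds$bad_mask) # linear indices, 1-based
  }
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(ds$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  path <- sub("\\.(json|dat)$", "", path)
  json_path <- paste0(path, ".json")
  if (!file.exists(json_path)) {
    stop_eegmvpa(paste0("Container sidecar not found: ", json_path))
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  required <- c("schema", "schema_version", "dims", "sfreq", "times",
                "labels", "conditions", "channels", "data_file")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop_eegmvpa(sprintf(
      "Container schema mismatch: expected keys [%s]; found [%s]; missing [%s].",
      paste(required, collapse = ", "),
      paste(names(meta), collapse = ", "),
      paste(missing, collapse = ", ")),
      class = "eegmvpa_schema_error")
  }
  if (!identical(meta$schema, "eegmvpa-epochs")) {
    stop_eegmvpa(paste0("Container schema mismatch: found schema '",
                        meta$schema, "', expected 'eegmvpa-epochs'."),
                 class = "eegmvpa_schema_error")
  }
  dims <- as.integer(meta$dims)
  dat_path <- file.path(dirname(json_path), meta$data_file)
  if (!file.exists(dat_path)) {
    stop_eegmvpa(paste0("Container data file not found: ", dat_path))
  }
  n <- prod(dims)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = n + 1L, size = 8L, endian = "little")
  if (length(vals) != n) {
    stop_eegmvpa(sprintf(
      "Container data length %d does not match dims product %d.",
      length(vals), n), class = "eegmvpa_schema_error")
  }
  bad_mask <- NULL
  if (!is.null(meta$bad_mask_which) && length(meta$bad_mask_which)) {
    bad_mask <- matrix(FALSE, dims[1], dims[2])
    bad_mask[as.integer(meta$bad_mask_which)] <- TRUE
  }
  eeg_epochs(
    data = array(vals, dim = dims),
    times = meta$times, sfreq = meta$sfreq,
    labels = meta$labels, channels = as_tibble(meta$channels),
    subject_id = meta$subject_id %||% "S01",
    conditions = meta$conditions, bad_mask = bad_mask
  )
}
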