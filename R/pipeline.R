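#' Assemble a pipeline run configuration
#'
#' Collects every knob of an end-to-end run: the simulation block (or paths
#' to existing native containers), preprocessing, the artifact-rejection
#' toggle, the decoding comparisons and the group-inference settings. The
#' master `seed` fans out deterministically to every stage, subject,
#' repetition and permutation, so identical configs reproduce identical
#' outputs.
#'
#' @param simulation a [sim_config()], or a character vector of container
#'   base paths to read with [read_epochs()].
#' @param preprocessing a [preproc_config()].
#' @param analysis_window decoding window (ms), cropped after
#'   preprocessing.
#' @param reject run automatic artifact rejection?
#' @param pairs named list of `c(target, control)` decoding pairs.
#' @param paired list of `c(name_a, name_b)` referencing `pairs` for the
#'   paired accuracy-difference test.
#' @param cross named list of `c(target, control, test)` cross
#'   classification specs.
#' @param tg named list of `c(target, control, test)` temporal
#'   generalization specs.
#' @param k,n_repetitions,lambda decoding settings; see
#'   [decode_timecourse()].
#' @param n_perm,z_crit,e_power,h_power group-inference settings; see
#'   [group_decode_test()].
#' @param seed master seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(simulation = sim_config(),
                       preprocessing = preproc_config(),
                       analysis_window = c(-100, 500),
                       reject = TRUE,
                       pairs = list(
                         hands_vs_animals = c("hands", "animals"),
                         tools_vs_animals = c("tools", "animals"),
                         hands_vs_feet = c("hands", "feet"),
                         tools_vs_feet = c("tools", "feet")
                       ),
                       paired = list(c("tools_vs_animals", "hands_vs_animals")),
                       cross = list(
                         train_tools_test_hands = c("tools", "animals", "hands"),
                         train_hands_test_tools = c("hands", "animals", "tools")
                       ),
                       tg = list(),
                       k = 10L, n_repetitions = 20L, lambda = NULL,
                       n_perm = 100L, z_crit = 1.96,
                       e_power = 0.5, h_power = 2,
                       seed = 1L) {
  cfg <- structure(list(
    simulation = simulation, preprocessing = preprocessing,
    analysis_window = as.numeric(analysis_window), reject = isTRUE(reject),
    pairs = pairs, paired = paired, cross = cross, tg = tg,
    k = as.integer(k), n_repetitions = as.integer(n_repetitions),
    lambda = lambda, n_perm = as.integer(n_perm), z_crit = z_crit,
    e_power = e_power, h_power = h_power, seed = as.integer(seed)
  ), class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (inherits(cfg$simulation, "sim_config")) {
    known <- cfg$simulation$conditions
    referenced <- unique(c(unlist(cfg$pairs), unlist(cfg$cross), unlist(cfg$tg)))
    bad <- setdiff(referenced, known)
    if (length(bad)) {
      stop_eegmvpa(paste0("Config references unknown condition(s): ",
                          paste(bad, collapse = ", ")))
    }
  }
  bad_pairs <- setdiff(unlist(cfg$paired), names(cfg$pairs))
  if (length(bad_pairs)) {
    stop_eegmvpa(paste0("`paired` references unknown pair name(s): ",
                        paste(bad_pairs, collapse = ", ")))
  }
  invisible(cfg)
}

#' Read a run configuration from YAML or JSON
#'
#' The file holds the same blocks as [run_config()]; `simulation` and
#' `preprocessing` sub-blocks are passed to [sim_config()] and
#' [preproc_config()]. Effects are given as lists with fields
#' `conditions`, `window`, `amplitude` and optional `envelope`,
#' `topography_seed`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  sim_block <- raw$simulation %||% list()
  if (!is.null(sim_block$effects)) {
    sim_block$effects <- lapply(sim_block$effects, function(ef) {
      do.call(effect_spec, ef)
    })
  }
  args <- raw
  args$simulation <- do.call(sim_config, sim_block)
  args$preprocessing <- do.call(preproc_config, raw$preprocessing %||% list())
  as_pairlist <- function(x) lapply(x, unlist)
  for (f in c("pairs", "paired", "cross", "tg")) {
    if (!is.null(args[[f]])) args[[f]] <- as_pairlist(args[[f]])
  }
  do.call(run_config, args)
}

write_result_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

write_zmap_outputs <- function(zm, name, out_dir) {
  files <- character(0)
  zcsv <- file.path(out_dir, paste0(name, "_zmap.csv"))
  write_result_csv(tidy(zm), zcsv)
  cjson <- file.path(out_dir, paste0(name, "_clusters.json"))
  jsonlite::write_json(zm$clusters, cjson, digits = NA, pretty = TRUE)
  c(files, zcsv, cjson)
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> preprocess -> reject -> decode -> group
#' inference -> report from a single configuration, writing CSV/JSON
#' artifacts and a run manifest (config hash, package version, per-stage
#' seeds and timings, file inventory with checksums) into `out_dir`.
#' Identical config and seed reproduce identical outputs.
#'
#' @param config a [run_config()], or a path readable by
#'   [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly, as a list; also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("eegmvpa_run_")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  files <- character(0)
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop_eegmvpa(sprintf("Pipeline stage '%s' failed: %s", stage,
                           conditionMessage(e)))
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # --- simulate / load ------------------------------------------------
  datasets <- clock("simulate", {
    if (inherits(config$simulation, "sim_config")) {
      lapply(simulate_study(config$simulation), `[[`, "epochs")
    } else {
      lapply(config$simulation, read_epochs)
    }
  })

  # --- preprocess (resample/filter/reref/crop/baseline) ---------------
  datasets <- clock("preprocess", lapply(datasets, preprocess,
                                         config = config$preprocessing))

  # --- artifact rejection --------------------------------------------
  rejection <- NULL
  if (config$reject) {
    rejection <- clock("reject", lapply(datasets, reject_artifacts))
    datasets <- lapply(rejection, `[[`, "epochs")
    rej_summary <- dplyr::bind_rows(
      lapply(seq_along(rejection), function(s) {
        dplyr::mutate(glance(rejection[[s]]$report), subject = s,
                      .before = 1)
      }))
    f <- write_result_csv(rej_summary, file.path(out_dir, "rejection_summary.csv"))
    files <- c(files, f)
  }

  # --- crop to analysis window ---------------------------------------
  datasets <- lapply(datasets, eeg_crop, window = config$analysis_window)

  # --- decoding + group stats -----------------------------------------
  pair_results <- list()
  for (nm in names(config$pairs)) {
    pr <- config$pairs[[nm]]
    pair_results[[nm]] <- clock(paste0("decode_", nm), group_decode_test(
      datasets, condition_pair(pr[1], pr[2]), k = config$k,
      n_repetitions = config$n_repetitions, n_perm = config$n_perm,
      lambda = config$lambda, seed = derive_seed(config$seed, 11L, match(nm, names(config$pairs))),
      z_crit = config$z_crit, e_power = config$e_power,
      h_power = config$h_power))
    files <- c(files, write_zmap_outputs(pair_results[[nm]], nm, out_dir))
    acc_csv <- file.path(out_dir, paste0(nm, "_accuracy.csv"))
    m <- pair_results[[nm]]$subject_acc
    acc_df <- tibble(
      subject = rep(seq_len(dim(m)[1]), times = dim(m)[2] * dim(m)[3]),
      time = rep(rep(datasets[[1]]$times, each = dim(m)[1]), times = dim(m)[3]),
      repetition = rep(seq_len(dim(m)[3]), each = dim(m)[1] * dim(m)[2]),
      accuracy = as.vector(m))
    files <- c(files, write_result_csv(acc_df, acc_csv))
  }

  for (sp in config$paired) {
    nm <- paste0("paired_", sp[1], "_minus_", sp[2])
    res <- clock(nm, paired_accuracy_test(
      pair_results[[sp[1]]], pair_results[[sp[2]]], n_perm = config$n_perm,
      seed = derive_seed(config$seed, 12L, 1L), z_crit = config$z_crit,
      e_power = config$e_power, h_power = config$h_power))
    files <- c(files, write_zmap_outputs(res, nm, out_dir))
  }

  for (nm in names(config$cross)) {
    sp <- config$cross[[nm]]
    res <- clock(paste0("cross_", nm), group_cross_test(
      datasets, condition_pair(sp[1], sp[2]), sp[3],
      n_repetitions = config$n_repetitions, n_perm = config$n_perm,
      lambda = config$lambda,
      seed = derive_seed(config$seed, 13L, match(nm, names(config$cross))),
      z_crit = config$z_crit, tg = FALSE, e_power = config$e_power,
      h_power = config$h_power))
    files <- c(files, write_zmap_outputs(res, paste0("cross_", nm), out_dir))
  }

  for (nm in names(config$tg)) {
    sp <- config$tg[[nm]]
    res <- clock(paste0("tg_", nm), group_cross_test(
      datasets, condition_pair(sp[1], sp[2]), sp[3],
      n_repetitions = config$n_repetitions, n_perm = config$n_perm,
      lambda = config$lambda,
      seed = derive_seed(config$seed, 14L, match(nm, names(config$tg))),
      z_crit = config$z_crit, tg = TRUE, e_power = config$e_power,
      h_power = config$h_power))
    files <- c(files, write_zmap_outputs(res, paste0("tg_", nm), out_dir))
  }

  # --- report + manifest ----------------------------------------------
  files <- c(files, report_tables(out_dir))

  cfg_tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(serialize_config(config), cfg_tmp, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("eegmvpa")),
    config = serialize_config(config),
    config_hash = unname(tools::md5sum(cfg_tmp)),
    master_seed = config$seed,
    timings_s = timings,
    files = lapply(stats::setNames(nm = basename(unique(files))), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

serialize_config <- function(config) {
  out <- unclass(config)
  if (inherits(out$simulation, "sim_config")) {
    sim <- unclass(out$simulation)
    sim$effects <- lapply(sim$effects, unclass)
    out$simulation <- sim
  }
  if (inherits(out$preprocessing, "preproc_config")) {
    out$preprocessing <- unclass(out$preprocessing)
  }
  out
}

#' Regenerate the cluster report tables of a finished run
#'
#' Collects every `*_clusters.json` in `run_dir` into per-comparison CSV
#' tables (cluster onset/offset, peak time, peak z, peak accuracy) plus an
#' onset-latency summary across comparisons. Idempotent: re-running does
#' not change existing tables.
#'
#' @param run_dir directory holding pipeline artifacts.
#' @return character vector of written file paths.
#' @export
report_tables <- function(run_dir) {
  cluster_files <- sort(list.files(run_dir, "_clusters\\.json$",
                                   full.names = TRUE))
  if (!length(cluster_files)) {
    stop_eegmvpa(paste0("No cluster artifacts found in ", run_dir))
  }
  all_rows <- list()
  for (f in cluster_files) {
    comparison <- sub("_clusters\\.json$", "", basename(f))
    cl <- jsonlite::read_json(f, simplifyVector = TRUE)
    cl <- as_tibble(cl)
    if (nrow(cl)) cl <- dplyr::mutate(cl, comparison = comparison, .before = 1)
    else cl$comparison <- character(0)
    all_rows[[comparison]] <- cl
  }
  peaks <- dplyr::bind_rows(all_rows)
  peak_path <- file.path(run_dir, "report_peaks.csv")
  write_result_csv(peaks, peak_path)
  onsets <- if (nrow(peaks)) {
    onset_any <- rep(NA_real_, nrow(peaks))
    for (col in intersect(c("onset", "onset_train"), names(peaks))) {
      onset_any <- ifelse(is.na(onset_any), peaks[[col]], onset_any)
    }
    peaks |>
      dplyr::mutate(.onset_any = onset_any) |>
      dplyr::group_by(.data$comparison) |>
      dplyr::summarise(first_onset = min(.data$.onset_any),
                       n_clusters = dplyr::n(), .groups = "drop")
  } else {
    tibble(comparison = character(0), first_onset = numeric(0),
           n_clusters = integer(0))
  }
  onset_path <- file.path(run_dir, "report_onsets.csv")
  write_result_csv(onsets, onset_path)
  c(peak_path, onset_path)
}
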