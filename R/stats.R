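#' Threshold-free cluster enhancement
#'
#' Integrates suprathreshold cluster extent and height over all thresholds:
#' `TFCE(p) = sum_{h = dh, 2dh, ... <= v(p)} e(p, h)^E * h^H * dh`, where
#' `e(p, h)` is the size of the connected suprathreshold component
#' containing `p` at height `h`. Defaults `E = 0.5`, `H = 2` are the
#' method's standard parameters; the integration step defaults to
#' 1/100 of the map's maximum magnitude. Signed maps are handled by
#' transforming the positive and negative parts separately and recombining
#' with sign. Connectivity is 2-neighbour for vectors and 4-neighbour for
#' matrices.
#'
#' @param x numeric vector (timecourse) or matrix (train x test grid);
#'   baseline (e.g. chance accuracy 0.5) must already be subtracted.
#' @param e_power extent exponent E.
#' @param h_power height exponent H.
#' @param dh integration step; `NULL` for `max(abs(x)) / 100`.
#' @return TFCE-transformed map, same shape as `x`.
#' @export
tfce <- function(x, e_power = 0.5, h_power = 2, dh = NULL) {
  if (any(!is.finite(x))) stop_eegmvpa("`x` contains non-finite values.")
  dims <- dim(x) %||% c(length(x), 1L)
  if (length(dims) != 2L) stop_eegmvpa("`x` must be a vector or matrix.")
  vmax <- max(abs(x))
  if (vmax == 0) return(x * 0)
  step <- dh %||% (vmax / 100)
  if (step <= 0) stop_eegmvpa("`dh` must be positive.")
  pos <- tfce_nonneg_cpp(as.vector(pmax(x, 0)), dims[1], dims[2],
                         e_power, h_power, step)
  neg <- tfce_nonneg_cpp(as.vector(pmax(-x, 0)), dims[1], dims[2],
                         e_power, h_power, step)
  out <- pos - neg
  if (!is.null(dim(x))) dim(out) <- dim(x) else out <- as.vector(out)
  out
}

#' Maximal-statistic permutation null
#'
#' Builds the permutation null of the maximal (and minimal) TFCE statistic:
#' for each permutation, `map_fn(i)` must return the group-average,
#' baseline-subtracted map recomputed under the i-th label permutation; the
#' map is TFCE-transformed and its maximum and minimum over all points are
#' recorded.
#'
#' @param map_fn function of the permutation index returning a numeric map
#'   (vector or matrix).
#' @param n_perm number of permutations.
#' @param e_power,h_power,dh TFCE parameters, see [tfce()].
#' @return list with numeric vectors `max` and `min`, each of length
#'   `n_perm`.
#' @export
permutation_null <- function(map_fn, n_perm = 100L, e_power = 0.5,
                             h_power = 2, dh = NULL) {
  null_max <- numeric(n_perm)
  null_min <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    tf <- tfce(map_fn(i), e_power, h_power, dh)
    null_max[i] <- max(tf)
    null_min[i] <- min(tf)
  }
  list(max = null_max, min = null_min)
}

#' Rank-based z-map from a maximal-statistic null
#'
#' Per point, one-tailed rank p-values are computed against the null of
#' maxima (positive tail) and minima (negative tail) with add-one
#' smoothing: `p+ = (1 + #\{null_max >= v\}) / (n_perm + 1)`, analogously
#' `p-` against the minima. The z-score is `qnorm(1 - p)` for the dominant
#' (smaller-p) tail, signed accordingly and floored at zero evidence: a
#' point that is extreme in neither tail gets z = 0, not a spuriously
#' negative z. With `n_perm = 100` the attainable |z| is capped at
#' `qnorm(100/101) = 2.33` (2 d.p.), the ceiling characteristic of
#' 100-permutation maximal-statistic maps.
#'
#' @param observed_tfce TFCE-transformed observed map (vector or matrix).
#' @param null_max,null_min null samples from [permutation_null()].
#' @return numeric z map, same shape as `observed_tfce`.
#' @export
z_from_null <- function(observed_tfce, null_max, null_min) {
  n_perm <- length(null_max)
  v <- as.vector(observed_tfce)
  p_plus <- (1 + vapply(v, function(x) sum(null_max >= x), numeric(1))) /
    (n_perm + 1)
  p_minus <- (1 + vapply(v, function(x) sum(null_min <= x), numeric(1))) /
    (n_perm + 1)
  cap <- n_perm / (n_perm + 1)
  p_plus <- pmin(p_plus, cap)
  p_minus <- pmin(p_minus, cap)
  z_plus <- qnorm(1 - p_plus)
  z_minus <- qnorm(1 - p_minus)
  z <- ifelse(z_plus >= z_minus, pmax(z_plus, 0), -pmax(z_minus, 0))
  if (!is.null(dim(observed_tfce))) dim(z) <- dim(observed_tfce)
  z
}

#' Extract significant clusters from a z-map
#'
#' Finds maximal contiguous runs (1-D; 2-neighbour) or 4-connected
#' components (2-D) of points with `|z| > z_crit`, splitting at sign
#' changes so each cluster has a coherent direction. Each cluster reports
#' onset/offset, the peak location (largest |z|, ties broken by the
#' underlying statistic, then by earliest time), peak z and — when an
#' accuracy map is supplied — the peak's underlying accuracy.
#'
#' @param z numeric z map (vector or matrix).
#' @param z_crit significance cutoff (default 1.96, two-tailed p < .05).
#' @param times timepoints (ms) for axis labelling; defaults to indices.
#' @param accuracy optional map of underlying accuracies, same shape.
#' @return a tibble with one row per cluster. 1-D columns: `cluster`,
#'   `sign`, `onset`, `offset`, `peak_time`, `peak_z`, `peak_accuracy`,
#'   `n_points`. 2-D columns use `onset_train`/`offset_train`/
#'   `onset_test`/`offset_test`/`peak_train_time`/`peak_test_time`.
#' @export
extract_clusters <- function(z, z_crit = 1.96, times = NULL,
                             accuracy = NULL) {
  if (any(!is.finite(z))) stop_eegmvpa("`z` contains non-finite values.")
  two_d <- !is.null(dim(z)) && all(dim(z) > 1)
  dims <- dim(z) %||% c(length(z), 1L)
  times <- times %||% seq_len(dims[1])
  sig <- abs(as.vector(z)) > z_crit
  # split at sign changes: label positive and negative excursions separately
  lab_pos <- label_components_cpp(sig & as.vector(z) > 0, dims[1], dims[2])
  lab_neg <- label_components_cpp(sig & as.vector(z) < 0, dims[1], dims[2])
  lab <- lab_pos
  lab[lab_neg > 0] <- lab_neg[lab_neg > 0] + max(lab_pos)
  if (!any(lab > 0)) {
    return(if (two_d) tibble(
      cluster = integer(0), sign = integer(0),
      onset_train = numeric(0), offset_train = numeric(0),
      onset_test = numeric(0), offset_test = numeric(0),
      peak_train_time = numeric(0), peak_test_time = numeric(0),
      peak_z = numeric(0), peak_accuracy = numeric(0), n_points = integer(0)
    ) else tibble(
      cluster = integer(0), sign = integer(0), onset = numeric(0),
      offset = numeric(0), peak_time = numeric(0), peak_z = numeric(0),
      peak_accuracy = numeric(0), n_points = integer(0)
    ))
  }
  zv <- as.vector(z)
  accv <- if (is.null(accuracy)) rep(NA_real_, length(zv)) else as.vector(accuracy)
  rows <- lapply(sort(unique(lab[lab > 0])), function(ell) {
    idx <- which(lab == ell)
    peak <- idx[order(-abs(zv[idx]), -abs(accv[idx] - 0.5), idx)][1]
    if (two_d) {
      rc <- arrayInd(idx, dims)
      prc <- arrayInd(peak, dims)
      tibble(
        sign = sign(zv[peak]),
        onset_train = times[min(rc[, 1])], offset_train = times[max(rc[, 1])],
        onset_test = times[min(rc[, 2])], offset_test = times[max(rc[, 2])],
        peak_train_time = times[prc[1, 1]], peak_test_time = times[prc[1, 2]],
        peak_z = zv[peak], peak_accuracy = accv[peak],
        n_points = length(idx)
      )
    } else {
      tibble(
        sign = sign(zv[peak]),
        onset = times[min(idx)], offset = times[max(idx)],
        peak_time = times[peak], peak_z = zv[peak],
        peak_accuracy = accv[peak], n_points = length(idx)
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  srt_col <- if (two_d) "onset_train" else "onset"
  out <- out[order(out[[srt_col]]), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  dplyr::relocate(out, cluster)
}

new_zmap <- function(z, times, mask, clusters, accuracy = NULL,
                     per_rep_z = NULL, z_crit = 1.96, analysis = NA_character_) {
  structure(list(
    z = z, times = times, mask = mask, clusters = clusters,
    accuracy = accuracy, per_rep_z = per_rep_z, z_crit = z_crit,
    analysis = analysis
  ), class = "zmap")
}

#' @export
print.zmap <- function(x, ...) {
  cat(sprintf("<zmap> %s: %s, %d significant point(s) (|z| > %g), %d cluster(s)\n",
              x$analysis,
              if (is.null(dim(x$z))) sprintf("%d timepoints", length(x$z))
              else sprintf("%d x %d grid", nrow(x$z), ncol(x$z)),
              sum(x$mask), x$z_crit, nrow(x$clusters)))
  invisible(x)
}

#' Average z-maps across repetitions
#'
#' The final z-map of an analysis is the arithmetic mean of the per
#' repetition z-maps; the significance mask and clusters are recomputed on
#' the averaged map.
#'
#' @param zmaps list of numeric maps (all the same shape), or a list of
#'   `zmap` objects.
#' @param times,accuracy,z_crit see [extract_clusters()].
#' @param analysis label carried in the result.
#' @return a `zmap` built on the averaged z values.
#' @export
average_zmaps <- function(zmaps, times = NULL, accuracy = NULL,
                          z_crit = 1.96, analysis = "averaged") {
  if (inherits(zmaps[[1]], "zmap")) {
    times <- times %||% zmaps[[1]]$times
    zmaps <- lapply(zmaps, `[[`, "z")
  }
  zbar <- Reduce(`+`, zmaps) / length(zmaps)
  times <- times %||% seq_len(if (is.null(dim(zbar))) length(zbar) else nrow(zbar))
  mask <- abs(zbar) > z_crit
  clusters <- extract_clusters(zbar, z_crit, times, accuracy)
  new_zmap(zbar, times, mask, clusters, accuracy = accuracy,
           per_rep_z = zmaps, z_crit = z_crit, analysis = analysis)
}

# permute condition labels across trials within one dataset (seeded)
permute_labels <- function(labels, seed) {
  with_seed(seed, sample(labels))
}

#' Group-level decoding test against chance
#'
#' The full group inference for one condition pair: per repetition, each
#' subject's cross-validated decoding timecourse is computed with a fresh
#' fold assignment, subject maps are averaged, chance (0.5) is subtracted
#' and the map is TFCE-transformed; a maximal-statistic null is built by
#' permuting condition labels across trials independently within each
#' subject and recomputing the whole group map `n_perm` times; rank-based
#' z-scores follow [z_from_null()]. The repetition z-maps are averaged and
#' thresholded at `z_crit`.
#'
#' @param datasets list of [eeg_epochs()] (one per subject), already
#'   preprocessed and cropped to the analysis window.
#' @param pair a [condition_pair()].
#' @param k fold count for the cross-validation.
#' @param n_repetitions fold-assignment repetitions (each with its own
#'   permutation null).
#' @param n_perm permutations per repetition.
#' @param lambda shrinkage intensity or `NULL` (Ledoit-Wolf).
#' @param seed master seed.
#' @param z_crit significance cutoff.
#' @param e_power,h_power,dh TFCE parameters.
#' @return a `zmap`; also carries `subject_acc`, the
#'   `[n_subjects x n_times x n_repetitions]` array of observed per-subject
#'   accuracy maps, and `mean_accuracy`.
#' @export
group_decode_test <- function(datasets, pair, k = 10L, n_repetitions = 20L,
                              n_perm = 100L, lambda = NULL, seed = 1L,
                              z_crit = 1.96, e_power = 0.5, h_power = 2,
                              dh = NULL) {
  if (length(datasets) < 2L) stop_eegmvpa("Need at least 2 subjects.")
  lam <- if (is.null(lambda)) -1 else lambda
  n_sub <- length(datasets)
  times <- datasets[[1]]$times
  nt <- length(times)

  subs <- lapply(datasets, function(ds) {
    sub <- select_conditions(ds, c(pair$target, pair$control))
    list(feats = sub$data[, scalp_channels(sub), , drop = FALSE],
         labels = sub$labels)
  })

  subject_acc <- array(NA_real_, c(n_sub, nt, n_repetitions))
  zmaps <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    obs <- matrix(NA_real_, n_sub, nt)
    for (s in seq_len(n_sub)) {
      fold <- make_balanced_folds(subs[[s]]$labels, k,
                                  derive_seed(seed, 301L, r, s))
      y1 <- as.integer(subs[[s]]$labels == pair$target)
      obs[s, ] <- as.vector(decode_cv_cpp(subs[[s]]$feats, y1, fold, lam))
    }
    subject_acc[, , r] <- obs
    obs_map <- colMeans(obs) - 0.5
    obs_tfce <- tfce(obs_map, e_power, h_power, dh)
    # permutation null: labels permuted across trials within each subject;
    # all permutations of one subject decoded in a single batched call
    null_sum <- matrix(0, n_perm, nt)
    for (s in seq_len(n_sub)) {
      n_tr <- length(subs[[s]]$labels)
      Y1 <- matrix(0L, n_tr, n_perm)
      FOLD <- matrix(0L, n_tr, n_perm)
      for (i in seq_len(n_perm)) {
        yp <- permute_labels(subs[[s]]$labels,
                             derive_seed(seed, 501L, r, i * 1000L + s))
        Y1[, i] <- as.integer(yp == pair$target)
        FOLD[, i] <- make_balanced_folds(yp, k, derive_seed(seed, 502L, r,
                                                            i * 1000L + s))
      }
      null_sum <- null_sum + decode_cv_batch_cpp(subs[[s]]$feats, Y1, FOLD, lam)
    }
    null_maps <- null_sum / n_sub - 0.5
    null_max <- numeric(n_perm)
    null_min <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      tf <- tfce(null_maps[i, ], e_power, h_power, dh)
      null_max[i] <- max(tf)
      null_min[i] <- min(tf)
    }
    zmaps[[r]] <- z_from_null(obs_tfce, null_max, null_min)
  }
  mean_accuracy <- apply(subject_acc, 2, mean)
  out <- average_zmaps(zmaps, times = times, accuracy = mean_accuracy,
                       z_crit = z_crit,
                       analysis = paste0("group decode: ", format(pair)))
  out$subject_acc <- subject_acc
  out$mean_accuracy <- mean_accuracy
  out$pair <- pair
  out
}

#' Group-level cross-classification / temporal-generalization test
#'
#' Same inference machinery as [group_decode_test()], but the per-subject
#' map is a cross-classification score (train on `train_pair`, test on
#' `test_condition`; [cross_classify_timecourse()]) or, with
#' `tg = TRUE`, the full temporal-generalization matrix. The permutation
#' null permutes the labels of the training-pair trials within each
#' subject.
#'
#' @inheritParams group_decode_test
#' @param train_pair a [condition_pair()] to train on.
#' @param test_condition held-out condition to test on.
#' @param tg compute the full train x test grid?
#' @return a `zmap` (1-D, or 2-D when `tg = TRUE`) with `subject_acc` and
#'   `mean_accuracy` attached.
#' @export
group_cross_test <- function(datasets, train_pair, test_condition,
                             n_repetitions = 20L, n_perm = 100L,
                             lambda = NULL, seed = 1L, z_crit = 1.96,
                             tg = FALSE, e_power = 0.5, h_power = 2,
                             dh = NULL) {
  if (length(datasets) < 2L) stop_eegmvpa("Need at least 2 subjects.")
  lam <- if (is.null(lambda)) -1 else lambda
  n_sub <- length(datasets)
  times <- datasets[[1]]$times
  nt <- length(times)

  subs <- lapply(datasets, function(ds) {
    scalp <- scalp_channels(ds)
    tr <- select_conditions(ds, c(train_pair$target, train_pair$control))
    te <- select_conditions(ds, test_condition)
    list(train_feats = tr$data[, scalp, , drop = FALSE],
         labels = tr$labels,
         test_feats = te$data[, scalp, , drop = FALSE])
  })

  map_dim <- if (tg) c(nt, nt) else nt
  one_map <- function(s, labels, sub_seed) {
    idx <- balance_subsample(labels, train_pair, sub_seed)
    y1 <- as.integer(labels[idx] == train_pair$target)
    out <- cross_decode_cpp(subs[[s]]$train_feats[idx, , , drop = FALSE],
                            y1, subs[[s]]$test_feats, lam, tg)
    if (tg) out else out[, 1]
  }

  subject_acc <- array(NA_real_, c(n_sub, prod(map_dim), n_repetitions))
  zmaps <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    obs <- matrix(NA_real_, n_sub, prod(map_dim))
    for (s in seq_len(n_sub)) {
      obs[s, ] <- as.vector(one_map(s, subs[[s]]$labels,
                                    derive_seed(seed, 401L, r, s)))
    }
    subject_acc[, , r] <- obs
    obs_map <- colMeans(obs) - 0.5
    dim(obs_map) <- if (tg) map_dim else NULL
    obs_tfce <- tfce(obs_map, e_power, h_power, dh)
    null <- permutation_null(function(i) {
      pm <- matrix(NA_real_, n_sub, prod(map_dim))
      for (s in seq_len(n_sub)) {
        yp <- permute_labels(subs[[s]]$labels,
                             derive_seed(seed, 601L, r, i * 1000L + s))
        pm[s, ] <- as.vector(one_map(s, yp,
                                     derive_seed(seed, 602L, r, i * 1000L + s)))
      }
      m <- colMeans(pm) - 0.5
      dim(m) <- if (tg) map_dim else NULL
      m
    }, n_perm, e_power, h_power, dh)
    zmaps[[r]] <- z_from_null(obs_tfce, null$max, null$min)
  }
  mean_accuracy <- apply(subject_acc, 2, mean)
  dim(mean_accuracy) <- if (tg) map_dim else NULL
  out <- average_zmaps(zmaps, times = times, accuracy = mean_accuracy,
                       z_crit = z_crit,
                       analysis = sprintf("group %s: train %s, test %s",
                                          if (tg) "TG" else "cross",
                                          format(train_pair), test_condition))
  out$subject_acc <- subject_acc
  out$mean_accuracy <- mean_accuracy
  out$train_pair <- train_pair
  out$test_condition <- test_condition
  out
}

#' Paired accuracy-difference test between two analyses
#'
#' Tests, per timepoint, whether decoding accuracy for pair A differs from
#' pair B across subjects. The statistic is the subject-average of the
#' per-subject accuracy difference; the null swaps the A/B assignment
#' within random subsets of subjects (a sign-flip of each subject's
#' difference), with TFCE + maximal-statistic correction and rank-based z
#' as in [group_decode_test()]. Positive z means A > B. Requires the two
#' inputs to share times, subjects and repetition count (e.g. two
#' [group_decode_test()] results computed on the same datasets).
#'
#' @param res_a,res_b `zmap` results from [group_decode_test()] carrying
#'   `subject_acc`.
#' @param n_perm sign-flip permutations per repetition.
#' @param seed master seed.
#' @param z_crit,e_power,h_power,dh inference parameters, see
#'   [group_decode_test()].
#' @return a `zmap` of the A - B difference; `accuracy` holds the mean
#'   difference map.
#' @export
paired_accuracy_test <- function(res_a, res_b, n_perm = 100L, seed = 1L,
                                 z_crit = 1.96, e_power = 0.5, h_power = 2,
                                 dh = NULL) {
  a <- res_a$subject_acc
  b <- res_b$subject_acc
  if (!identical(dim(a), dim(b))) stop_eegmvpa("Subject accuracy arrays differ in shape.")
  if (!isTRUE(all.equal(res_a$times, res_b$times))) {
    stop_eegmvpa("Time axes differ.")
  }
  n_sub <- dim(a)[1]
  n_rep <- dim(a)[3]
  zmaps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    diffs <- a[, , r] - b[, , r] # [subjects x points]
    obs_tfce <- tfce(colMeans(diffs), e_power, h_power, dh)
    null <- permutation_null(function(i) {
      flips <- with_seed(derive_seed(seed, 701L, r, i),
                         sample(c(-1, 1), n_sub, replace = TRUE))
      colMeans(diffs * flips)
    }, n_perm, e_power, h_power, dh)
    zmaps[[r]] <- z_from_null(obs_tfce, null$max, null$min)
  }
  mean_diff <- apply(a - b, 2, mean)
  out <- average_zmaps(zmaps, times = res_a$times, accuracy = 0.5 + mean_diff,
                       z_crit = z_crit, analysis = "paired accuracy difference")
  out$mean_difference <- mean_diff
  out
}
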