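# Shared fixture builders. Everything is generated in code; no data files.

# A small epoched dataset built directly from an array (no simulation).
toy_epochs <- function(data, sfreq = 100, t0 = NULL, labels = NULL,
                       roles = NULL) {
  d <- dim(data)
  t0 <- t0 %||% 0
  times <- t0 + (0:(d[3] - 1)) * 1000 / sfreq
  labels <- labels %||% rep(c("a", "b"), length.out = d[1])
  roles <- roles %||% rep("scalp", d[2])
  ch <- tibble::tibble(
    name = sprintf("C%02d", seq_len(d[2])), role = roles,
    x = cos(seq_len(d[2])), y = sin(seq_len(d[2])),
    z = rep(0.5, d[2])
  )
  eeg_epochs(data, times, sfreq, labels, ch)
}

# Fast 2-condition simulation for decoding tests.
quick_sim <- function(seed, n_trials = 24, n_ch = 6, sfreq = 50,
                      window = c(-100, 100), effects = list(),
                      conditions = c("a", "b"), noise_model = "ar1",
                      jitter = 0) {
  cfg <- sim_config(
    n_subjects = 1, n_trials_per_condition = n_trials,
    conditions = conditions, n_scalp_channels = n_ch, sfreq = sfreq,
    epoch_window = window, effects = effects, noise_model = noise_model,
    amplitude_jitter_sd = jitter, seed = seed
  )
  simulate_subject(cfg, 1)
}

# Brute-force TFCE oracle: explicit loop over the height grid with
# components found by flood fill. Mirrors the definition, not the
# implementation (which uses union-find in C++).
tfce_oracle <- function(x, e_power = 0.5, h_power = 2, dh) {
  dims <- dim(x) %||% c(length(x), 1L)
  one_sided <- function(v) {
    out <- numeric(length(v))
    vmax <- max(v)
    n_steps <- floor(vmax / dh + 1e-9)
    for (step in seq_len(n_steps)) {
      h <- step * dh
      up <- v >= h
      lab <- integer(length(v))
      cur <- 0L
      for (i in seq_along(v)) {
        if (!up[i] || lab[i] > 0) next
        cur <- cur + 1L
        queue <- i
        while (length(queue)) {
          j <- queue[[1]]; queue <- queue[-1]
          if (lab[j] > 0) next
          lab[j] <- cur
          rc <- arrayInd(j, dims)
          nb <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          for (d in nb) {
            r2 <- rc[1] + d[1]; c2 <- rc[2] + d[2]
            if (r2 >= 1 && r2 <= dims[1] && c2 >= 1 && c2 <= dims[2]) {
              j2 <- (c2 - 1) * dims[1] + r2
              if (up[j2] && lab[j2] == 0) queue <- c(queue, j2)
            }
          }
        }
      }
      sizes <- tabulate(lab)
      out[up] <- out[up] + sizes[lab[up]]^e_power * h^h_power * dh
    }
    out
  }
  res <- one_sided(pmax(as.vector(x), 0)) - one_sided(pmax(-as.vector(x), 0))
  if (!is.null(dim(x))) dim(res) <- dim(x)
  res
}

# Brute-force auto-threshold oracle: evaluate the objective at every
# candidate threshold directly from the definition.
auto_threshold_oracle <- function(signals) {
  p2p <- apply(signals, 1, function(v) max(v) - min(v))
  med <- apply(signals, 2, median)
  cands <- sort(unique(p2p))
  J <- vapply(cands, function(th) {
    kept <- signals[p2p <= th, , drop = FALSE]
    sum((colMeans(kept) - med)^2)
  }, numeric(1))
  best <- which(J <= min(J))
  cands[best[length(best)]] # largest threshold among minimisers
}

# Brute-force shrinkage-LDA oracle from the stated formulas, using
# explicitly inverted covariance.
lda_oracle_predict <- function(x, y, lambda, newdata) {
  i1 <- y == 1
  mu1 <- colMeans(x[i1, , drop = FALSE])
  mu0 <- colMeans(x[!i1, , drop = FALSE])
  xc <- x
  xc[i1, ] <- sweep(x[i1, , drop = FALSE], 2, mu1)
  xc[!i1, ] <- sweep(x[!i1, , drop = FALSE], 2, mu0)
  S <- crossprod(xc) / nrow(x)
  Sh <- (1 - lambda) * S + lambda * (sum(diag(S)) / ncol(x)) * diag(ncol(x))
  w <- solve(Sh, mu1 - mu0)
  b <- -sum(w * (mu1 + mu0) / 2)
  as.integer(as.matrix(newdata) %*% w + b > 0)
}
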